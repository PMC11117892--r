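#' @title Region masks for the four cancer characteristics
#' @name regions
#' @description
#' Each characteristic is scored over its own pixel region in the RoI frame:
#' echogenicity over the lesion interior (all pixels inside the boundary
#' polygon), calcification over 3x3 windows around each annotated
#' calcification point, and shape/margin over a thin ribbon straddling the
#' lesion boundary (the two signs share the geometry and differ only in the
#' categorical label used for grouping).
NULL

REGION_CHARACTERISTICS <- c("calcification", "echogenicity", "shape", "margin")

new_region_mask <- function(mask, characteristic, empty = !any(mask)) {
  characteristic <- check_vocab(characteristic, REGION_CHARACTERISTICS,
                                "characteristic")
  structure(list(mask = mask, characteristic = characteristic, empty = empty),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask '%s': %d of %d pixels%s>\n",
              x$characteristic, sum(x$mask), length(x$mask),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Lesion interior mask (echogenicity region)
#'
#' Pixels whose centers lie inside or on the closed boundary polygon
#' (even-odd rule).
#'
#' @param annotation a [lesion_annotation()] in RoI coordinates.
#' @param shape `c(rows, cols)` of the heatmap/image the mask pairs with.
#' @return A `region_mask` tagged `"echogenicity"`.
#' @export
lesion_interior_mask <- function(annotation, shape) {
  m <- polygon_mask(annotation$boundary, shape)
  if (!any(m)) {
    stop("lesion polygon covers no pixel centers in the given shape",
         call. = FALSE)
  }
  new_region_mask(m, "echogenicity")
}

#' Calcification region mask
#'
#' Union of the 3x3 windows centered at each calcification point, clipped to
#' the image. With no points the mask is returned empty and flagged, so that
#' images without the sign can be excluded from calcification statistics.
#'
#' @param points m x 2 matrix of calcification points (0-based row, col),
#'   possibly empty, or a [lesion_annotation()].
#' @param shape `c(rows, cols)`.
#' @return A `region_mask` tagged `"calcification"`.
#' @export
calcification_region <- function(points, shape) {
  if (inherits(points, "lesion_annotation")) points <- points$calcifications
  points <- as_coord_matrix(points, "calcifications")
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(points))) {
    r <- round_half_up(points[i, 1]); c <- round_half_up(points[i, 2])
    rs <- intersect((r - 1):(r + 1), 0:(shape[1] - 1))
    cs <- intersect((c - 1):(c + 1), 0:(shape[2] - 1))
    m[rs + 1L, cs + 1L] <- TRUE
  }
  new_region_mask(m, "calcification", empty = nrow(points) == 0L)
}

#' Boundary ribbon mask (shape / margin region)
#'
#' A band straddling the lesion boundary: with `ARwh` the mean of the
#' axis-aligned bounding rectangle's width and height, the half-width is
#' `w = max(1, round(0.02 * ARwh))` and the ribbon is the interior mask
#' dilated by a radius-`w` disk minus the interior eroded by the same disk,
#' i.e. inner and outer bands of 2% of `ARwh` each with the original
#' boundary in the center.
#'
#' @inheritParams lesion_interior_mask
#' @param characteristic `"shape"` or `"margin"` — the two signs share the
#'   ribbon geometry and differ only in the grouping label.
#' @param width_fraction band half-width as a fraction of `ARwh`.
#' @return A `region_mask` tagged with `characteristic`; the half-width used
#'   is attached as attribute `"half_width"`.
#' @export
boundary_ribbon <- function(annotation, shape,
                            characteristic = c("shape", "margin"),
                            width_fraction = 0.02) {
  characteristic <- match.arg(characteristic)
  b <- annotation$boundary
  interior <- polygon_mask(b, shape)
  if (!any(interior)) {
    stop("lesion polygon covers no pixel centers in the given shape",
         call. = FALSE)
  }
  arwh <- mean(c(max(b[, 1]) - min(b[, 1]) + 1,
                 max(b[, 2]) - min(b[, 2]) + 1))
  w <- max(1L, round_half_up(width_fraction * arwh))
  ribbon <- dilate_mask(interior, w) & !erode_mask(interior, w)
  out <- new_region_mask(ribbon, characteristic)
  attr(out, "half_width") <- w
  out
}

#' Write a region mask as a 1-bit-style PNG with a JSON sidecar
#'
#' @param region a `region_mask`.
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @export
write_region_mask <- function(region, path) {
  png::writePNG(region$mask * 1, path)
  jsonlite::write_json(
    list(characteristic = region$characteristic, empty = region$empty,
         n_pixels = sum(region$mask)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
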