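#' @title Region-of-interest preparation
#' @name preprocess
#' @description
#' The classifier consumes fixed-size crops around the lesion rather than the
#' full ultrasound frame. The crop is the axis-aligned bounding box of the
#' annotated boundary, enlarged by a margin (default 8% of each side length,
#' split evenly per side and rounded outward) so that the tumor
#' microenvironment is included, then resized with bicubic interpolation to
#' the classifier input size. Annotations are remapped into the resized frame
#' so that region masks can be built in classifier coordinates.
NULL

#' Crop the lesion region of interest with margin
#'
#' Computes the axis-aligned bounding box of the boundary vertices, enlarges
#' each side by `margin_fraction` of its length (half per side, rounded
#' outward) and clips to the image bounds, warning when clipping occurs.
#'
#' @param image a [gs_image()] or matrix.
#' @param annotation a [lesion_annotation()] in the image's coordinate frame.
#' @param margin_fraction nonnegative margin as a fraction of each bounding
#'   box side (default 0.08, i.e. +8%).
#' @return A list with elements `image` (the cropped [gs_image()]) and
#'   `transform` (crop offset, crop size and — after [resize_roi()] /
#'   [prepare_roi()] — scale factors).
#' @export
crop_roi <- function(image, annotation, margin_fraction = 0.08) {
  px <- as_pixels(image)
  stopifnot(margin_fraction >= 0)
  b <- annotation$boundary
  if (nrow(b) == 0) stop("empty boundary", call. = FALSE)
  r0 <- floor(min(b[, 1])); r1 <- ceiling(max(b[, 1]))
  c0 <- floor(min(b[, 2])); c1 <- ceiling(max(b[, 2]))
  if (r1 <= r0 || c1 <= c0) {
    stop("degenerate lesion boundary: zero-area bounding box", call. = FALSE)
  }
  pad_r <- ceiling(margin_fraction * (r1 - r0 + 1) / 2 - 1e-9)
  pad_c <- ceiling(margin_fraction * (c1 - c0 + 1) / 2 - 1e-9)
  want <- c(r0 - pad_r, r1 + pad_r, c0 - pad_c, c1 + pad_c)
  got <- c(max(want[1], 0), min(want[2], nrow(px) - 1),
           max(want[3], 0), min(want[4], ncol(px) - 1))
  if (any(want != got)) {
    warning("RoI crop clipped to the image bounds", call. = FALSE)
  }
  cropped <- px[(got[1]:got[2]) + 1L, (got[3]:got[4]) + 1L, drop = FALSE]
  transform <- list(offset = c(got[1], got[3]),
                    crop_size = c(nrow(cropped), ncol(cropped)),
                    scale = c(1, 1))
  id <- if (inherits(image, "gs_image")) paste0(image$id, "_roi") else "roi"
  list(image = gs_image(cropped, id = id), transform = transform)
}

#' Resize an image with bicubic interpolation
#'
#' Uses the Keys cubic-convolution kernel (a = -0.5) with half-pixel-center
#' alignment and clamps the (possibly overshooting) result to `[0, 255]`.
#'
#' @param image a [gs_image()] or matrix.
#' @param target `c(rows, cols)` or a scalar for a square output; each
#'   dimension must be at least 8.
#' @return A [gs_image()] of exactly the target size.
#' @export
resize_roi <- function(image, target) {
  px <- as_pixels(image)
  if (length(target) == 1L) target <- c(target, target)
  target <- as.integer(target)
  if (any(target < 8L)) stop("target size must be at least 8 x 8", call. = FALSE)
  out <- clamp(resample_matrix(px, target, "bicubic"), 0, 255)
  gs_image(out, id = if (inherits(image, "gs_image")) image$id else "resized")
}

#' Remap an annotation through a crop/resize transform
#'
#' Each vertex and calcification point is translated by the crop offset,
#' scaled by the resize factors and rounded to the nearest pixel; categorical
#' labels are unchanged. Points outside the crop raise an error.
#'
#' @param annotation a [lesion_annotation()] in original-image coordinates.
#' @param transform the transform returned by [crop_roi()] / [prepare_roi()].
#' @return The remapped [lesion_annotation()] in RoI coordinates.
#' @export
remap_annotation <- function(annotation, transform) {
  map_points <- function(p) {
    if (nrow(p) == 0) return(p)
    q <- sweep(p, 2, transform$offset)
    out_of_crop <- q[, 1] < -0.5 | q[, 1] > transform$crop_size[1] - 0.5 |
      q[, 2] < -0.5 | q[, 2] > transform$crop_size[2] - 0.5
    if (any(out_of_crop)) {
      stop("annotation point falls outside the crop region", call. = FALSE)
    }
    q <- sweep(q, 2, transform$scale, `*`)
    round_half_up(q)
  }
  lesion_annotation(boundary = map_points(annotation$boundary),
                    calcifications = map_points(annotation$calcifications),
                    shape = annotation$shape, margin = annotation$margin,
                    echo = annotation$echo, class = annotation$class,
                    image = annotation$image, check_simple = FALSE)
}

#' Prepare one RoI sample for the classifier
#'
#' Convenience wrapper chaining [crop_roi()], [resize_roi()] and
#' [remap_annotation()].
#'
#' @inheritParams crop_roi
#' @param size classifier input size, `c(rows, cols)` or a scalar.
#' @return A list of class `roi_sample` with elements `image`, `annotation`
#'   (both in the resized RoI frame) and `transform`.
#' @export
prepare_roi <- function(image, annotation, size = 224, margin_fraction = 0.08) {
  if (length(size) == 1L) size <- c(size, size)
  crop <- crop_roi(image, annotation, margin_fraction)
  crop$transform$scale <- size / crop$transform$crop_size
  resized <- resize_roi(crop$image, size)
  structure(list(image = resized,
                 annotation = remap_annotation(annotation, crop$transform),
                 transform = crop$transform),
            class = "roi_sample")
}

#' Prepare a whole dataset of RoI samples
#'
#' Maps [prepare_roi()] over a dataset tibble (as returned by
#' [read_dataset()]), replacing the `image` and `annotation` list-columns
#' with their RoI-frame versions.
#'
#' @param dataset tibble with list-columns `image` and `annotation`.
#' @inheritParams prepare_roi
#' @return The dataset tibble with RoI-frame images and annotations.
#' @export
prepare_dataset <- function(dataset, size = 224, margin_fraction = 0.08) {
  rois <- purrr::map2(dataset$image, dataset$annotation,
                      ~prepare_roi(.x, .y, size = size,
                                   margin_fraction = margin_fraction))
  dataset$image <- purrr::map(rois, "image")
  dataset$annotation <- purrr::map(rois, "annotation")
  dataset
}
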