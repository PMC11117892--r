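#' @title Core domain objects: grayscale images and lesion annotations
#' @name data-model
#' @description
#' camlink works with 8-bit grayscale ultrasound images carrying exactly one
#' lesion each, together with a radiologist-style annotation: the lesion
#' boundary polygon, the locations of calcification flecks, and categorical
#' labels for shape, margin and echogenicity pattern plus the
#' histopathological ground-truth class.
#'
#' All coordinates are 0-based `(row, col)` pairs addressing pixel centers;
#' polygons are closed implicitly (the last vertex connects back to the
#' first).
NULL

CLASS_LEVELS  <- c("benign", "malignant")
SHAPE_LEVELS  <- c("regular", "irregular")
MARGIN_LEVELS <- c("circumscribed", "not_circumscribed")
ECHO_LEVELS   <- c("uniform", "non_uniform")
OUTCOME_LEVELS <- c("TN", "TP", "FP", "FN")

#' Construct a grayscale image
#'
#' @param pixels numeric matrix of intensities on the 8-bit scale `[0, 255]`,
#'   at least 8 x 8.
#' @param id image identifier.
#' @return An object of class `gs_image`.
#' @export
gs_image <- function(pixels, id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie within [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, id = as.character(id)), class = "gs_image")
}

#' @export
print.gs_image <- function(x, ...) {
  cat(sprintf("<gs_image '%s' %d x %d, range [%.0f, %.0f]>\n",
              x$id, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gs_image <- function(x) dim(x$pixels)

# Accept a gs_image or a bare matrix wherever pixel data is needed.
as_pixels <- function(image) {
  if (inherits(image, "gs_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a gs_image or a matrix", call. = FALSE)
}

as_coord_matrix <- function(x, field) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) {
    return(matrix(numeric(0), 0, 2))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2) x <- matrix(x, 1, 2)
  if (!is.matrix(x) || ncol(x) != 2 || !is.numeric(x)) {
    stop(sprintf("field '%s' must be an n x 2 numeric matrix of (row, col)",
                 field), call. = FALSE)
  }
  storage.mode(x) <- "double"
  unname(x)
}

check_vocab <- function(value, levels, field) {
  if (length(value) != 1L || !value %in% levels) {
    stop(sprintf("field '%s' must be one of {%s}, got '%s'",
                 field, paste(levels, collapse = ", "),
                 paste(value, collapse = ",")), call. = FALSE)
  }
  value
}

#' Construct a lesion annotation
#'
#' @param boundary n x 2 numeric matrix (n >= 3) of boundary vertices in
#'   0-based `(row, col)` coordinates; the polygon is closed implicitly and
#'   must be simple (non-self-intersecting).
#' @param calcifications m x 2 matrix of calcification points (possibly
#'   empty).
#' @param shape one of `"regular"`, `"irregular"`.
#' @param margin one of `"circumscribed"`, `"not_circumscribed"`.
#' @param echo one of `"uniform"`, `"non_uniform"`.
#' @param class ground-truth class, `"benign"` or `"malignant"`.
#' @param image identifier of the annotated image.
#' @param image_shape optional `c(rows, cols)`; when given, all vertices and
#'   points are checked to lie inside the image bounds.
#' @param check_simple check the boundary polygon for self-intersections
#'   (disabled internally after pixel rounding, which may make a valid
#'   polygon graze itself).
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(boundary, calcifications = NULL,
                              shape, margin, echo, class,
                              image = "image", image_shape = NULL,
                              check_simple = TRUE) {
  boundary <- as_coord_matrix(boundary, "boundary")
  if (nrow(boundary) < 3L) {
    stop("field 'boundary' needs at least 3 vertices", call. = FALSE)
  }
  calcifications <- as_coord_matrix(calcifications, "calcifications")
  if (check_simple && !polygon_is_simple(boundary)) {
    stop("field 'boundary' is self-intersecting", call. = FALSE)
  }
  ann <- structure(
    list(image = as.character(image),
         boundary = boundary,
         calcifications = calcifications,
         shape = check_vocab(shape, SHAPE_LEVELS, "shape"),
         margin = check_vocab(margin, MARGIN_LEVELS, "margin"),
         echo = check_vocab(echo, ECHO_LEVELS, "echo"),
         class = check_vocab(class, CLASS_LEVELS, "class")),
    class = "lesion_annotation")
  if (!is.null(image_shape)) validate_annotation_bounds(ann, image_shape)
  ann
}

validate_annotation_bounds <- function(ann, image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  pts <- rbind(ann$boundary, ann$calcifications)
  bad <- pts[, 1] < 0 | pts[, 1] > nr - 1 | pts[, 2] < 0 | pts[, 2] > nc - 1
  if (any(bad)) {
    stop(sprintf("annotation '%s': %d point(s) outside the %d x %d image",
                 ann$image, sum(bad), nr, nc), call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.lesion_annotation <- function(x, ...) {
  cat(sprintf(
    "<lesion_annotation '%s': %d vertices, %d calcification(s), %s/%s/%s, %s>\n",
    x$image, nrow(x$boundary), nrow(x$calcifications),
    x$shape, x$margin, x$echo, x$class))
  invisible(x)
}

#' Read and write lesion annotations as JSON
#'
#' One JSON file per image with fields `image`, `boundary` (array of
#' `[row, col]` pairs), `calcifications`, `shape`, `margin`, `echo`, `class`.
#' Reading validates vocabularies and polygon simplicity; malformed files
#' raise errors naming the offending field.
#'
#' @param path file path.
#' @param image_shape optional `c(rows, cols)` for bounds checking on read.
#' @return `read_annotation()` returns a [lesion_annotation()];
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path, image_shape = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse annotation JSON '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  required <- c("image", "boundary", "shape", "margin", "echo", "class")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("annotation '", path, "' is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lesion_annotation(boundary = raw$boundary,
                    calcifications = raw$calcifications,
                    shape = raw$shape, margin = raw$margin,
                    echo = raw$echo, class = raw$class,
                    image = raw$image, image_shape = image_shape)
}

#' @rdname read_annotation
#' @param annotation a [lesion_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "lesion_annotation"))
  obj <- list(image = annotation$image,
              boundary = annotation$boundary,
              calcifications = annotation$calcifications,
              shape = annotation$shape,
              margin = annotation$margin,
              echo = annotation$echo,
              class = annotation$class)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read and write 8-bit grayscale images (PNG or TIFF)
#'
#' Multi-channel files are collapsed to grayscale by channel averaging.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param id identifier for the resulting image (defaults to the file name).
#' @return `read_image()` returns a [gs_image()]; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  gs_image(round(arr * 255),
           id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id)
}

#' @rdname read_image
#' @param image a [gs_image()].
#' @export
write_image <- function(image, path) {
  px <- as_pixels(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Classification outcome of a prediction
#'
#' Maps (true class, predicted class) to the standard 2 x 2 outcome under the
#' convention that malignant is the positive class: benign/benign is a true
#' negative (TN), malignant/malignant a true positive (TP), a benign lesion
#' predicted malignant a false positive (FP), and a malignant lesion
#' predicted benign a false negative (FN).
#'
#' @param true_class,predicted_class vectors over `{"benign", "malignant"}`
#'   (recycled to a common length).
#' @return Character vector over `{"TN", "TP", "FP", "FN"}`.
#' @export
#' @examples
#' outcome_of("benign", "benign")      # "TN"
#' outcome_of("malignant", "benign")   # "FN"
outcome_of <- function(true_class, predicted_class) {
  n <- max(length(true_class), length(predicted_class))
  true_class <- rep_len(as.character(true_class), n)
  predicted_class <- rep_len(as.character(predicted_class), n)
  ok <- true_class %in% CLASS_LEVELS & predicted_class %in% CLASS_LEVELS
  if (!all(ok)) {
    stop("class labels must be 'benign' or 'malignant'", call. = FALSE)
  }
  dplyr::case_when(
    true_class == "benign" & predicted_class == "benign"       ~ "TN",
    true_class == "malignant" & predicted_class == "malignant" ~ "TP",
    true_class == "benign" & predicted_class == "malignant"    ~ "FP",
    TRUE                                                       ~ "FN")
}

#' Assemble a per-image prediction record
#'
#' @param id image identifier.
#' @param true_class,predicted_class class labels.
#' @param pre_softmax named numeric vector of raw class scores.
#' @param confidence post-softmax probability of the predicted class.
#' @return A one-row tibble with the outcome attached.
#' @export
prediction_record <- function(id, true_class, predicted_class,
                              pre_softmax, confidence) {
  stopifnot(confidence >= 0, confidence <= 1)
  tibble::tibble(
    id = as.character(id),
    true_class = true_class,
    predicted_class = predicted_class,
    outcome = outcome_of(true_class, predicted_class),
    score_benign = unname(pre_softmax["benign"]),
    score_malignant = unname(pre_softmax["malignant"]),
    confidence = confidence)
}
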