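#' @title Synthetic ultrasound-like lesion images with ground truth
#' @name synthetic
#' @description
#' The generator emulates the image features the analysis pipeline keys on:
#' a speckle-textured background (smoothed exponential multiplicative
#' noise), a darker (hypoechoic) lesion bounded by a star-shaped polar curve
#' whose harmonic irregularity controls the shape label, optional bright
#' Gaussian calcification flecks at recorded points, low-frequency interior
#' intensity patches for non-uniform echogenicity, and Gaussian blurring of
#' the lesion edge for non-circumscribed margins. Every image is emitted
#' with its full ground-truth annotation, and the default class rule couples
#' malignancy to the planted signs (irregular boundary or calcification) so
#' that the classification task is learnable and planted-saliency
#' expectations have a causal basis.
NULL

#' Specification of one synthetic lesion image
#'
#' @param size image side length in pixels (square image).
#' @param radius lesion radius range `c(lo, hi)` in pixels.
#' @param amplitude boundary irregularity amplitude as a fraction of the
#'   radius, in `[0, 0.5]`; 0 is a smooth ellipse-like lesion, values at or
#'   above 0.15 are labeled irregular.
#' @param n_calcifications range `c(lo, hi)` of calcification counts.
#' @param echo `"uniform"` or `"non_uniform"` interior texture.
#' @param blur Gaussian sigma (pixels) applied to the lesion edge; 0 gives a
#'   sharp, circumscribed margin.
#' @param id image identifier.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = 128L, radius = c(20, 36), amplitude = 0,
                           n_calcifications = c(0L, 0L), echo = "uniform",
                           blur = 0, id = "synthetic") {
  stopifnot(size >= 32L, length(radius) == 2L, radius[1] > 0,
            radius[2] >= radius[1],
            amplitude >= 0, amplitude <= 0.5,
            length(n_calcifications) == 2L, n_calcifications[1] >= 0,
            blur >= 0)
  check_vocab(echo, ECHO_LEVELS, "echo")
  # lesion (with irregularity and center jitter) must fit inside the image
  # with room for the +8% RoI margin
  if (radius[2] * (1 + amplitude) * 1.1 + 6 > size / 2) {
    stop("radius range does not fit the image with room for the RoI margin",
         call. = FALSE)
  }
  structure(list(size = as.integer(size), radius = radius,
                 amplitude = amplitude,
                 n_calcifications = as.integer(n_calcifications),
                 echo = echo, blur = blur, id = as.character(id)),
            class = "synthetic_spec")
}

# Default class rule: malignant iff the boundary is irregular or at least
# one calcification is planted.
default_class_rule <- function(amplitude, n_calc) {
  if (amplitude >= 0.15 || n_calc >= 1L) "malignant" else "benign"
}

#' Generate one synthetic lesion image with its annotation
#'
#' Deterministic given the seed: the same `(spec, seed)` pair reproduces the
#' image and annotation bit for bit.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return List with `image` (a [gs_image()]) and `annotation` (a
#'   [lesion_annotation()]).
#' @export
generate_lesion_image <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_(seed, {
    size <- spec$size
    R <- runif(1, spec$radius[1], spec$radius[2])
    theta <- 2 * pi * (0:63) / 64
    pert <- rep(0, 64)
    if (spec$amplitude > 0) {
      for (j in 2:5) {
        pert <- pert + runif(1, -1, 1) * cos(j * theta + runif(1, 0, 2 * pi))
      }
      pert <- pert / max(abs(pert))
    }
    r <- R * (1 + spec$amplitude * pert)
    center <- size / 2 + runif(2, -4, 4)
    # vertex coordinates kept at 1e-4 px precision so annotations survive
    # JSON round-trips exactly
    boundary <- round(cbind(center[1] + r * cos(theta),
                            center[2] + r * sin(theta)), 4)

    # speckle background: smoothed exponential multiplicative noise
    bg <- gaussian_blur(matrix(rexp(size^2), size, size), 1.5)
    bg <- bg / mean(bg) * 150

    hard <- polygon_mask(boundary, c(size, size)) * 1
    soft <- if (spec$blur > 0) gaussian_blur(hard, spec$blur) else hard
    img <- bg * (1 - 0.55 * soft)                     # hypoechoic interior

    if (spec$echo == "non_uniform") {
      patch <- gaussian_blur(matrix(rnorm(size^2), size, size), 5)
      patch <- patch / max(abs(patch))
      img <- img * (1 + 0.35 * patch * soft)
    }

    n_calc <- if (spec$n_calcifications[1] == spec$n_calcifications[2]) {
      spec$n_calcifications[1]
    } else {
      sample(spec$n_calcifications[1]:spec$n_calcifications[2], 1L)
    }
    points <- matrix(numeric(0), 0, 2)
    if (n_calc > 0L) {
      tp <- runif(n_calc, 0, 2 * pi)
      # interpolate the boundary radius at each angle (keep flecks well
      # inside the lesion, away from the boundary ribbon)
      rp <- approx(x = c(theta, 2 * pi), y = c(r, r[1]), xout = tp)$y
      rho <- runif(n_calc, 0.15, 0.5) * rp
      points <- round_half_up(cbind(center[1] + rho * cos(tp),
                                    center[2] + rho * sin(tp)))
      for (i in seq_len(n_calc)) {
        pr <- points[i, 1]; pc <- points[i, 2]
        rs <- max(0, pr - 4):min(size - 1, pr + 4)
        cs <- max(0, pc - 4):min(size - 1, pc + 4)
        d2 <- outer((rs - pr)^2, (cs - pc)^2, `+`)
        img[rs + 1L, cs + 1L] <- img[rs + 1L, cs + 1L] +
          110 * exp(-d2 / (2 * 1.2^2))
      }
    }

    image <- gs_image(round_half_up(clamp(img, 0, 255)), id = spec$id)
    annotation <- lesion_annotation(
      boundary = boundary, calcifications = points,
      shape = if (spec$amplitude >= 0.15) "irregular" else "regular",
      margin = if (spec$blur > 0) "not_circumscribed" else "circumscribed",
      echo = spec$echo,
      class = default_class_rule(spec$amplitude, n_calc),
      image = spec$id, image_shape = c(size, size))
    list(image = image, annotation = annotation)
  })
}

#' Generate a synthetic dataset
#'
#' Draws per-image parameter configurations so that the requested class
#' balance is met exactly (benign images: near-circular, no calcifications;
#' malignant images: irregular boundary, planted calcifications, or both),
#' generates each image deterministically from a derived seed, and — when
#' `dir` is given — writes one PNG and one annotation JSON per image plus an
#' `index.csv` manifest.
#'
#' @param n number of images (>= 2).
#' @param balance benign fraction (default 0.5); the benign count is
#'   `round(balance * n)`.
#' @param dir output directory, or `NULL` to keep the dataset in memory.
#' @param size image side length.
#' @param radius lesion radius range in pixels; defaults to 16-28% of the
#'   image side so that lesions of any configured size fit with the RoI
#'   margin.
#' @param seed integer seed fixing the whole dataset.
#' @return A tibble manifest with one row per image: `id`, `class`, `shape`,
#'   `margin`, `echo`, `n_calcifications`, list-columns `image` and
#'   `annotation`, and (file mode) `image_path` / `annotation_path`.
#' @export
generate_dataset <- function(n, balance = 0.5, dir = NULL, size = 128L,
                             radius = size * c(0.16, 0.28), seed = 1L) {
  stopifnot(n >= 2, balance >= 0, balance <= 1)
  n_benign <- round(balance * n)
  n_malignant <- n - n_benign
  configs <- with_seed_(seed, {
    draw_config <- function(class) {
      if (class == "benign") {
        list(amplitude = runif(1, 0, 0.08), n_calc = 0L,
             blur = if (runif(1) < 0.7) 0 else 1.2,
             echo = if (runif(1) < 0.6) "uniform" else "non_uniform")
      } else {
        u <- runif(1)
        amp <- if (u < 0.75) runif(1, 0.15, 0.3) else runif(1, 0, 0.08)
        ncal <- if (u < 0.5 || u >= 0.75) sample(1:4, 1L) else 0L
        list(amplitude = amp, n_calc = ncal,
             blur = if (runif(1) < 0.3) 0 else 1.5,
             echo = if (runif(1) < 0.15) "uniform" else "non_uniform")
      }
    }
    classes <- sample(rep(c("benign", "malignant"), c(n_benign, n_malignant)))
    cfg <- purrr::map(classes, draw_config)
    list(classes = classes, cfg = cfg,
         seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- configs$cfg[[i]]
    id <- sprintf("syn_%04d", i)
    spec <- synthetic_spec(size = size, radius = radius,
                           amplitude = cf$amplitude,
                           n_calcifications = c(cf$n_calc, cf$n_calc),
                           echo = cf$echo, blur = cf$blur, id = id)
    gen <- generate_lesion_image(spec, seed = configs$seeds[i])
    stopifnot(gen$annotation$class == configs$classes[i])
    row <- tibble::tibble(
      id = id, class = gen$annotation$class, shape = gen$annotation$shape,
      margin = gen$annotation$margin, echo = gen$annotation$echo,
      n_calcifications = nrow(gen$annotation$calcifications),
      image = list(gen$image), annotation = list(gen$annotation))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      row$image_path <- file.path(dir, paste0(id, ".png"))
      row$annotation_path <- file.path(dir, paste0(id, ".json"))
      write_image(gen$image, row$image_path)
      write_annotation(gen$annotation, row$annotation_path)
    }
    rows[[i]] <- row
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    idx <- manifest |>
      dplyr::select("id", "class", "shape", "margin", "echo",
                    "n_calcifications", "image_path", "annotation_path")
    idx$image_path <- basename(idx$image_path)
    idx$annotation_path <- basename(idx$annotation_path)
    utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  }
  manifest
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir directory containing `index.csv` (or the path of the index
#'   file itself).
#' @return Tibble manifest with list-columns `image` and `annotation`.
#' @export
read_dataset <- function(dir) {
  index <- if (dir.exists(dir)) file.path(dir, "index.csv") else dir
  if (!file.exists(index)) stop("no index.csv found at ", dir, call. = FALSE)
  base <- dirname(index)
  idx <- utils::read.csv(index, stringsAsFactors = FALSE)
  idx <- tibble::as_tibble(idx)
  idx$image <- purrr::map(file.path(base, idx$image_path), read_image)
  idx$annotation <- purrr::map(file.path(base, idx$annotation_path),
                               read_annotation)
  idx
}

#' Annotation-driven oracle heatmap backend
#'
#' A backend that bypasses any learned model: its heatmap is exactly 1 on
#' the named characteristic region of the image's ground-truth annotation
#' (or all zero), and its prediction follows a configurable rule. Used for
#' exact recovery tests of the contribution statistics: with
#' `"calcification_hot"` the significant ratio over the calcification
#' region is 1 by construction and the boundary ribbon receives 0 wherever
#' the regions are disjoint.
#'
#' @param mode `"calcification_hot"`, `"interior_hot"` or `"zero"`.
#' @param prediction `"truth"` (predict the annotated class), a fixed class
#'   label, or a `function(annotation)` returning a class label.
#' @param input_size RoI frame size the oracle reports via [input_shape()].
#' @return An object of class `oracle_backend`.
#' @export
oracle_backend <- function(mode = c("calcification_hot", "interior_hot",
                                    "zero"),
                           prediction = "truth", input_size = 64L) {
  mode <- match.arg(mode)
  if (length(input_size) == 1L) input_size <- c(input_size, input_size)
  structure(list(mode = mode, prediction = prediction,
                 input_shape = as.integer(input_size)),
            class = "oracle_backend")
}

#' @export
print.oracle_backend <- function(x, ...) {
  cat(sprintf("<oracle_backend '%s', input %dx%d>\n", x$mode,
              x$input_shape[1], x$input_shape[2]))
  invisible(x)
}

#' @rdname backend-contract
#' @export
input_shape.oracle_backend <- function(backend) backend$input_shape

#' @rdname backend-contract
#' @export
n_classes.oracle_backend <- function(backend) 2L

#' @rdname predict_class
#' @export
predict_class.oracle_backend <- function(backend, image, annotation = NULL,
                                         ...) {
  rule <- backend$prediction
  cls <- if (is.function(rule)) {
    rule(annotation)
  } else if (identical(rule, "truth")) {
    if (is.null(annotation)) {
      stop("oracle prediction rule 'truth' needs the annotation",
           call. = FALSE)
    }
    annotation$class
  } else {
    check_vocab(rule, CLASS_LEVELS, "prediction")
  }
  scores <- setNames(c(-1, 1)[1L + (CLASS_LEVELS == cls)], CLASS_LEVELS)
  list(class = cls, confidence = unname(softmax(scores)[cls]),
       pre_softmax = scores)
}

#' @rdname generate_heatmap
#' @export
generate_heatmap.oracle_backend <- function(backend, image, annotation = NULL,
                                            class = NULL,
                                            method = c("egrad_cam",
                                                       "ablation_cam",
                                                       "grad_cam"),
                                            gate = c("all", "positive",
                                                     "top_mass"),
                                            p = 0.95, ...) {
  method <- match.arg(method)
  if (is.null(annotation) && backend$mode != "zero") {
    stop("oracle backend needs the annotation to plant its heatmap",
         call. = FALSE)
  }
  shape <- dim(as_pixels(image))
  values <- switch(backend$mode,
    zero = matrix(0, shape[1], shape[2]),
    calcification_hot = calcification_region(annotation, shape)$mask * 1,
    interior_hot = lesion_interior_mask(annotation, shape)$mask * 1)
  cls <- if (!is.null(class)) class
         else predict_class(backend, image, annotation)$class
  new_heatmap(values, method = method, class = cls, entropy_mode = "oracle")
}
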