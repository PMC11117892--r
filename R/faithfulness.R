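#' @title Heatmap faithfulness metrics
#' @name faithfulness
#' @description
#' A faithful heatmap should mark the pixels the classifier actually relies
#' on: feeding the classifier an *explanation map* — the input image
#' reweighted by the top-ranked heatmap pixels — should preserve (or raise)
#' its confidence. Three metrics quantify this: the average drop in
#' confidence, the percent of images whose confidence increases, and the
#' head-to-head win percentage between two methods.
NULL

#' Build an explanation map from an image and its heatmap
#'
#' Pixels are ranked by heatmap score (descending); the top
#' `ceil(top_fraction * N)` keep their heatmap weight, the rest are zeroed,
#' and the resulting weight map multiplies the original image elementwise.
#'
#' @param image a [gs_image()] or intensity matrix.
#' @param heatmap a `heatmap` (or matrix in `[0, 1]`) of the same shape.
#' @param top_fraction fraction of pixels retained, in `(0, 1]`
#'   (default 0.8).
#' @return The explanation map, as a [gs_image()] when `image` is one and as
#'   a plain matrix otherwise.
#' @export
explanation_map <- function(image, heatmap, top_fraction = 0.8) {
  px <- as_pixels(image)
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  stopifnot(all(dim(px) == dim(hv)),
            top_fraction > 0, top_fraction <= 1)
  n_keep <- ceiling(top_fraction * length(hv))
  weights <- hv
  if (n_keep < length(hv)) {
    ord <- order(hv, decreasing = TRUE)       # ties broken by pixel index
    weights[ord[seq.int(n_keep + 1L, length(hv))]] <- 0
  }
  out <- px * weights
  if (inherits(image, "gs_image")) {
    gs_image(out, id = paste0(image$id, "_explanation"))
  } else {
    out
  }
}

#' Average drop in confidence (percent)
#'
#' `mean over images of max(0, (Y - O) / Y) * 100`, where `Y` is the
#' confidence on the original image and `O` on its explanation map; images
#' whose confidence increases contribute zero. Lower is better.
#'
#' @param confidences numeric vector `Y` of original-image confidences
#'   (strictly positive).
#' @param explanation_confidences numeric vector `O` of the same length.
#' @return Percentage in `[0, 100]`.
#' @export
average_drop <- function(confidences, explanation_confidences) {
  stopifnot(length(confidences) == length(explanation_confidences),
            length(confidences) > 0)
  if (any(confidences <= 0)) {
    stop("original confidences must be strictly positive", call. = FALSE)
  }
  mean(pmax(0, (confidences - explanation_confidences) / confidences)) * 100
}

#' Percent increase in confidence
#'
#' Share of images whose confidence is strictly higher on the explanation
#' map than on the original image. Higher is better.
#'
#' @inheritParams average_drop
#' @return Percentage in `[0, 100]`.
#' @export
percent_increase <- function(confidences, explanation_confidences) {
  stopifnot(length(confidences) == length(explanation_confidences))
  if (length(confidences) == 0) stop("empty confidence lists", call. = FALSE)
  100 * sum(confidences < explanation_confidences) / length(confidences)
}

#' Head-to-head win percentage of two methods
#'
#' Per-image relative confidence drops (before clipping at zero) are
#' compared between two methods; method A wins on an image when its drop is
#' positive and strictly larger than B's (a larger positive drop means the
#' removed pixels mattered more). Ties and images where neither drop is
#' positive count for neither method; percentages are taken over all N
#' images.
#'
#' @param drops_a,drops_b per-image relative drops `(Y - O) / Y` of the two
#'   methods (unclipped).
#' @return Named numeric vector `c(win_a = , win_b = )`, percentages summing
#'   to at most 100.
#' @export
win_percent <- function(drops_a, drops_b) {
  stopifnot(length(drops_a) == length(drops_b))
  if (length(drops_a) == 0) stop("empty drop lists", call. = FALSE)
  n <- length(drops_a)
  win_a <- sum(drops_a > 0 & drops_a > drops_b)
  win_b <- sum(drops_b > 0 & drops_b > drops_a)
  c(win_a = 100 * win_a / n, win_b = 100 * win_b / n)
}

#' Evaluate heatmap faithfulness over a dataset
#'
#' For every image and method: classify, generate the heatmap of the
#' predicted class, build the explanation map, and record the confidence in
#' the originally predicted class for both inputs. Returns the three metrics
#' per method, with win percentages computed between the first two methods.
#'
#' @param dataset tibble with list-columns `image` and `annotation` in the
#'   RoI frame at the backend's input size.
#' @param backend a classifier backend.
#' @param methods heatmap methods to compare (the first two enter the win%
#'   comparison).
#' @param gate,p entropy gating settings for EGrad-CAM.
#' @param top_fraction fraction of pixels retained in explanation maps.
#' @return An object of class `faithfulness_report`: list with `summary`
#'   (tibble: method, n, average_drop, percent_increase, win_percent) and
#'   `per_image` (per-image confidences and drops).
#' @export
evaluate_faithfulness <- function(dataset, backend,
                                  methods = c("egrad_cam", "ablation_cam"),
                                  gate = "top_mass", p = 0.95,
                                  top_fraction = 0.8) {
  stopifnot(nrow(dataset) >= 1, length(methods) >= 1)
  n <- nrow(dataset)
  ids <- if ("id" %in% names(dataset)) as.character(dataset$id)
         else sprintf("image_%03d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    img <- dataset$image[[i]]
    ann <- dataset$annotation[[i]]
    pred <- predict_class(backend, img, annotation = ann)
    for (m in methods) {
      hm <- generate_heatmap(backend, img, annotation = ann,
                             class = pred$class, method = m,
                             gate = gate, p = p)
      expl <- explanation_map(img, hm, top_fraction)
      o <- class_confidence(backend, expl, pred$class)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = ids[i], method = m, predicted_class = pred$class,
        confidence = pred$confidence, explanation_confidence = o,
        drop = (pred$confidence - o) / pred$confidence)
    }
  }
  per_image <- dplyr::bind_rows(rows)
  summary <- per_image |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      average_drop = average_drop(.data$confidence,
                                  .data$explanation_confidence),
      percent_increase = percent_increase(.data$confidence,
                                          .data$explanation_confidence),
      .groups = "drop")
  if (length(methods) >= 2) {
    da <- per_image$drop[per_image$method == methods[1]]
    db <- per_image$drop[per_image$method == methods[2]]
    wins <- win_percent(da, db)
    summary$win_percent <- NA_real_
    summary$win_percent[summary$method == methods[1]] <- wins[["win_a"]]
    summary$win_percent[summary$method == methods[2]] <- wins[["win_b"]]
  }
  summary <- summary[match(methods, summary$method), ]
  structure(list(summary = summary, per_image = per_image,
                 top_fraction = top_fraction),
            class = "faithfulness_report")
}

#' @export
print.faithfulness_report <- function(x, ...) {
  cat(sprintf("<faithfulness_report: top %.0f%% of pixels, %d images>\n",
              100 * x$top_fraction,
              length(unique(x$per_image$id))))
  print(x$summary)
  invisible(x)
}
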