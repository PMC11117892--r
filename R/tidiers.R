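# broom-style tidiers for the fitted/report objects.

#' Tidy a contribution report
#'
#' @param x a `contribution_report`.
#' @param ... unused.
#' @return The summary tibble: one row per (characteristic, level, outcome).
#' @export
tidy.contribution_report <- function(x, ...) x$summary

#' One-line summary of a contribution report
#'
#' @inheritParams tidy.contribution_report
#' @return One-row tibble with image count, accuracy over the analyzed
#'   images, and the method settings.
#' @export
glance.contribution_report <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$per_image),
    accuracy = mean(x$per_image$outcome %in% c("TN", "TP")),
    method = x$method, gate = x$gate, threshold = x$threshold)
}

#' Tidy a faithfulness report
#'
#' @param x a `faithfulness_report`.
#' @param ... unused.
#' @return The per-method metrics tibble.
#' @export
tidy.faithfulness_report <- function(x, ...) x$summary

#' Tidy a trained tiny CNN fit
#'
#' @param x a `tiny_cnn_fit`.
#' @param ... unused.
#' @return The per-epoch training history tibble.
#' @export
tidy.tiny_cnn_fit <- function(x, ...) x$history

#' One-line summary of a trained tiny CNN fit
#'
#' @inheritParams tidy.tiny_cnn_fit
#' @return One-row tibble with training accuracy, TNR and TPR.
#' @export
glance.tiny_cnn_fit <- function(x, ...) x$metrics
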