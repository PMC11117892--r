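#' @title Plotting methods
#' @name plots
#' @description ggplot2 visualizations of images, heatmaps, region masks and
#'   contribution reports.
NULL

matrix_to_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(0:(nrow(m) - 1L), times = ncol(m)),
    col = rep(0:(ncol(m) - 1L), each = nrow(m)),
    !!value_name := as.vector(m))
}

#' @describeIn plots grayscale image raster.
#' @param object,x object to plot.
#' @param ... unused.
#' @export
autoplot.gs_image <- function(object, ...) {
  df <- matrix_to_df(object$pixels, "intensity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plots saliency heatmap (blue = no contribution, red = high).
#' @export
autoplot.heatmap <- function(object, ...) {
  df <- matrix_to_df(object$values, "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166ac", "#67a9cf", "#f7f7f7", "#ef8a62", "#b2182b"),
      limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (%s), class %s", object$method,
                                  object$entropy_mode, object$class),
                  x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' @describeIn plots heatmap overlaid on its image, with the lesion boundary
#'   and calcification points when an annotation is given.
#' @param image a [gs_image()].
#' @param heatmap a `heatmap` of the same shape.
#' @param annotation optional [lesion_annotation()] in the same frame.
#' @param alpha heatmap overlay opacity.
#' @export
plot_overlay <- function(image, heatmap, annotation = NULL, alpha = 0.45) {
  img_df <- matrix_to_df(as_pixels(image), "intensity")
  hm_df <- matrix_to_df(heatmap$values, "score")
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = img_df,
                         ggplot2::aes(x = .data$col, y = .data$row),
                         fill = grDevices::gray(img_df$intensity / 255)) +
    ggplot2::geom_raster(data = hm_df,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$score),
                         alpha = alpha) +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166ac", "#67a9cf", "#f7f7f7", "#ef8a62", "#b2182b"),
      limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score")
  if (!is.null(annotation)) {
    b <- tibble::tibble(row = annotation$boundary[, 1],
                        col = annotation$boundary[, 2])
    p <- p + ggplot2::geom_path(data = rbind(b, b[1, ]),
                                ggplot2::aes(x = .data$col, y = .data$row),
                                colour = "green", linewidth = 0.4)
    if (nrow(annotation$calcifications) > 0) {
      cc <- tibble::tibble(row = annotation$calcifications[, 1],
                          col = annotation$calcifications[, 2])
      p <- p + ggplot2::geom_point(data = cc,
                                   ggplot2::aes(x = .data$col, y = .data$row),
                                   colour = "red", shape = 4, size = 2)
    }
  }
  p
}

#' @describeIn plots categorical contribution grid per characteristic level
#'   and outcome.
#' @export
autoplot.contribution_report <- function(object, ...) {
  df <- object$summary |>
    dplyr::mutate(group = paste(.data$characteristic, .data$level, sep = ": "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$group,
                                   fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$avg_ratio), "-",
                     sprintf("%.2f", .data$avg_ratio))), size = 3) +
    ggplot2::scale_fill_manual(
      values = c("No" = "#f7f7f7", "Very Low" = "#fee5d9",
                 "Low" = "#fcae91", "Medium" = "#fb6a4a", "High" = "#cb181d"),
      drop = FALSE) +
    ggplot2::labs(x = "prediction outcome", y = NULL,
                  fill = "contribution",
                  title = sprintf("Characteristic contributions (%s, gate %s)",
                                  object$method, object$gate)) +
    ggplot2::theme_minimal()
}
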