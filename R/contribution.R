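#' @title Characteristic contribution statistics
#' @name contribution
#' @description
#' For each image the heatmap of the *predicted* class is scored over each
#' characteristic's region: the significant ratio `Rs` is the fraction of
#' region pixels whose heatmap score reaches the significance threshold
#' (default 0.5, the midpoint of the normalized scale). Ratios are grouped
#' by prediction outcome (TN/TP/FP/FN) and by characteristic level (e.g.
#' uniform vs non-uniform), averaged into `AvRs`, and graded into the
#' categories No / Very Low / Low / Medium / High.
NULL

CONTRIB_CATEGORIES <- c("No", "Very Low", "Low", "Medium", "High")

#' Significant-score ratio of a region
#'
#' `Rs = |{p in R : Hs(p) >= threshold}| / |R|`.
#'
#' @param heatmap a `heatmap` (or matrix in `[0, 1]`).
#' @param region a `region_mask` (or logical matrix) of the same shape.
#' @param threshold significance threshold on the normalized heatmap scale.
#' @return The ratio in `[0, 1]`.
#' @export
significant_ratio <- function(heatmap, region, threshold = 0.5) {
  hv <- if (inherits(heatmap, "heatmap")) heatmap$values else heatmap
  rm_ <- if (inherits(region, "region_mask")) region$mask else region
  stopifnot(all(dim(hv) == dim(rm_)))
  if (!any(rm_)) {
    stop("no annotated pixels for characteristic", call. = FALSE)
  }
  sum(hv[rm_] >= threshold) / sum(rm_)
}

#' Average significant ratio across images
#'
#' @param ratios numeric vector of per-image ratios in `[0, 1]`.
#' @return The arithmetic mean `AvRs`; an empty group is reported as absent
#'   (`NA`), not zero, so that "no contribution" (ratio exactly 0 with cases
#'   present) stays distinguishable from "no cases".
#' @export
average_ratio <- function(ratios) {
  if (length(ratios) == 0) return(NA_real_)
  stopifnot(all(ratios >= 0 & ratios <= 1))
  mean(ratios)
}

#' Categorize an average significant ratio
#'
#' Grades `AvRs` into contribution levels: exactly 0 is No; `(0, 0.2]` Very
#' Low; `(0.2, 0.35]` Low; `(0.35, 0.5)` Medium; `>= 0.5` High. The bounds
#' are implemented exactly as defined (Medium open, High closed at 0.5).
#'
#' @param avrs numeric vector of average ratios in `[0, 1]` (`NA` allowed
#'   for absent groups).
#' @return Ordered factor over No < Very Low < Low < Medium < High.
#' @export
#' @examples
#' categorize(c(0, 0.16, 0.31, 0.38, 0.5))
categorize <- function(avrs) {
  if (any(!is.na(avrs) & (avrs < 0 | avrs > 1))) {
    stop("average ratios must lie in [0, 1]", call. = FALSE)
  }
  lab <- dplyr::case_when(
    is.na(avrs)  ~ NA_character_,
    avrs == 0    ~ "No",
    avrs <= 0.2  ~ "Very Low",
    avrs <= 0.35 ~ "Low",
    avrs < 0.5   ~ "Medium",
    TRUE         ~ "High")
  factor(lab, levels = CONTRIB_CATEGORIES, ordered = TRUE)
}

#' Pixelwise mean of heatmaps
#'
#' Aggregates several heatmaps (e.g. all correctly classified cases of one
#' outcome) into a single average heatmap.
#'
#' @param heatmaps non-empty list of `heatmap`s of identical shape.
#' @return A `heatmap` whose values are the pixelwise arithmetic mean.
#' @export
aggregate_heatmaps <- function(heatmaps) {
  stopifnot(length(heatmaps) >= 1)
  vals <- purrr::map(heatmaps, function(h)
    if (inherits(h, "heatmap")) h$values else h)
  d <- dim(vals[[1]])
  if (!all(purrr::map_lgl(vals, ~all(dim(.x) == d)))) {
    stop("heatmaps must share one shape", call. = FALSE)
  }
  m <- Reduce(`+`, vals) / length(vals)
  first <- heatmaps[[1]]
  new_heatmap(m,
              method = if (inherits(first, "heatmap")) first$method else "grad_cam",
              class = if (inherits(first, "heatmap")) first$class else NA_character_,
              entropy_mode = "aggregate")
}

#' Run the full contribution analysis over a dataset
#'
#' For every image: classify, generate the heatmap for the *predicted*
#' class, build the applicable region masks from the ground-truth
#' annotation, and compute the significant ratio per characteristic. Images
#' lacking a characteristic (no calcification points) are excluded from that
#' characteristic's groups. Ratios are then grouped by (characteristic,
#' level, outcome), averaged and categorized, and aggregate heatmaps are
#' formed per outcome group.
#'
#' @param dataset tibble with list-columns `image` and `annotation` in the
#'   RoI frame at the backend's input size (see [prepare_dataset()]).
#' @param backend a classifier backend (trained `tiny_cnn` or
#'   [oracle_backend()]).
#' @param method,gate,p heatmap method and entropy gating, as in
#'   [generate_heatmap()].
#' @param threshold significance threshold for [significant_ratio()].
#' @param calcification_scoring `"union"` scores the union of all 3x3
#'   windows at once (the default); `"per_window"` scores each window
#'   separately and averages the per-window ratios.
#' @return An object of class `contribution_report`: list with `summary`
#'   (tibble: characteristic, level, outcome, n_cases, avg_ratio, category,
#'   featuremap_usage), `per_image` (per-image ratios and predictions),
#'   `aggregates` (named list of average heatmaps per outcome) and the
#'   method settings.
#' @export
run_contribution_analysis <- function(dataset, backend,
                                      method = c("egrad_cam", "ablation_cam",
                                                 "grad_cam"),
                                      gate = c("top_mass", "all", "positive"),
                                      p = 0.95, threshold = 0.5,
                                      calcification_scoring = c("union",
                                                                "per_window")) {
  method <- match.arg(method)
  gate <- match.arg(gate)
  calcification_scoring <- match.arg(calcification_scoring)
  n <- nrow(dataset)
  stopifnot(n >= 1)
  ids <- if ("id" %in% names(dataset)) as.character(dataset$id)
         else sprintf("image_%03d", seq_len(n))

  rows <- vector("list", n)
  heatmaps <- vector("list", n)
  for (i in seq_len(n)) {
    img <- dataset$image[[i]]
    ann <- dataset$annotation[[i]]
    pred <- predict_class(backend, img, annotation = ann)
    hm <- generate_heatmap(backend, img, annotation = ann,
                           class = pred$class, method = method,
                           gate = gate, p = p)
    heatmaps[[i]] <- hm
    shape <- dim(hm$values)
    calc <- calcification_region(ann, shape)
    rs_calc <- if (calc$empty) NA_real_ else {
      if (calcification_scoring == "union") {
        significant_ratio(hm, calc, threshold)
      } else {
        per_calcification_ratio(hm, ann, shape, threshold)
      }
    }
    interior <- lesion_interior_mask(ann, shape)
    ribbon <- boundary_ribbon(ann, shape, "shape")
    rows[[i]] <- tibble::tibble(
      id = ids[i],
      true_class = ann$class,
      predicted_class = pred$class,
      outcome = outcome_of(ann$class, pred$class),
      confidence = pred$confidence,
      echo = ann$echo, shape = ann$shape, margin = ann$margin,
      has_calcification = !calc$empty,
      rs_calcification = rs_calc,
      rs_echogenicity = significant_ratio(hm, interior, threshold),
      rs_shape = significant_ratio(hm, ribbon, threshold),
      rs_margin = rs_shape,
      featuremap_usage = attr(hm, "usage") %||% NA_real_)
  }
  per_image <- dplyr::bind_rows(rows)
  per_image$rs_margin <- per_image$rs_shape  # same ribbon, different grouping

  long <- dplyr::bind_rows(
    per_image |>
      dplyr::filter(.data$has_calcification) |>
      dplyr::transmute(.data$id, .data$outcome, .data$featuremap_usage,
                       characteristic = "calcification", level = "present",
                       rs = .data$rs_calcification),
    per_image |>
      dplyr::transmute(.data$id, .data$outcome, .data$featuremap_usage,
                       characteristic = "echogenicity", level = .data$echo,
                       rs = .data$rs_echogenicity),
    per_image |>
      dplyr::transmute(.data$id, .data$outcome, .data$featuremap_usage,
                       characteristic = "shape", level = .data$shape,
                       rs = .data$rs_shape),
    per_image |>
      dplyr::transmute(.data$id, .data$outcome, .data$featuremap_usage,
                       characteristic = "margin", level = .data$margin,
                       rs = .data$rs_margin))

  summary <- long |>
    dplyr::group_by(.data$characteristic, .data$level, .data$outcome) |>
    dplyr::summarise(n_cases = dplyr::n(),
                     avg_ratio = average_ratio(.data$rs),
                     featuremap_usage = mean(.data$featuremap_usage),
                     .groups = "drop") |>
    dplyr::mutate(category = categorize(.data$avg_ratio)) |>
    dplyr::select("characteristic", "level", "outcome", "n_cases",
                  "avg_ratio", "category", "featuremap_usage") |>
    dplyr::arrange(.data$characteristic, .data$level, .data$outcome)

  aggregates <- purrr::map(split(seq_len(n), per_image$outcome),
                           ~aggregate_heatmaps(heatmaps[.x]))

  structure(list(summary = summary, per_image = per_image,
                 aggregates = aggregates, method = method, gate = gate,
                 p = p, threshold = threshold),
            class = "contribution_report")
}

# Per-window variant: score each 3x3 calcification window separately and
# average the window ratios.
per_calcification_ratio <- function(hm, ann, shape, threshold) {
  pts <- ann$calcifications
  ratios <- vapply(seq_len(nrow(pts)), function(i) {
    win <- calcification_region(pts[i, , drop = FALSE], shape)
    significant_ratio(hm, win, threshold)
  }, numeric(1))
  mean(ratios)
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("<contribution_report: %s (gate %s), %d images, threshold %.2f>\n",
              x$method, x$gate, nrow(x$per_image), x$threshold))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write a contribution report summary as CSV
#'
#' One row per (characteristic, level, outcome) with columns `n_cases`,
#' `avg_ratio`, `category`, `featuremap_usage`; absent groups print `-`.
#'
#' @param report a `contribution_report`.
#' @param path output CSV path.
#' @export
write_report <- function(report, path) {
  df <- report$summary
  df$avg_ratio <- ifelse(is.na(df$avg_ratio), "-",
                         formatC(df$avg_ratio, digits = 6, format = "f"))
  df$featuremap_usage <- ifelse(is.na(df$featuremap_usage), "-",
                                formatC(df$featuremap_usage, digits = 6,
                                        format = "f"))
  df$category <- as.character(df$category)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
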