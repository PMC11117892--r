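#' @title Class-activation heatmaps: EGrad-CAM and Ablation-CAM
#' @name cam
#' @description
#' Both methods build a saliency heatmap as a rectified weighted sum of the
#' designated layer's feature maps; they differ in how the per-map weights
#' are obtained. EGrad-CAM weights map `k` by the plain sum of the class
#' score gradients over the map, and additionally *gates* the sum on the
#' Shannon entropy of each map, so that near-constant (uninformative) maps
#' are frozen out. Ablation-CAM weights map `k` by the relative drop in the
#' pre-softmax class score when the map is zeroed and the downstream network
#' re-run. Raw maps live at feature-layer resolution; [postprocess_heatmap()]
#' upsamples them bilinearly to input resolution and min-max normalizes to
#' `[0, 1]`.
NULL

HEATMAP_METHODS <- c("egrad_cam", "ablation_cam", "grad_cam")

as_map_array <- function(x, what = "maps") {
  if (is.list(x)) x <- simplify2array(x)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(what, " must be a list of matrices or an h x w x K array",
         call. = FALSE)
  }
  x
}

#' Gradient weights for Grad-CAM-style heatmaps
#'
#' The weight of feature map `k` for class `c` is the sum over all spatial
#' locations of `dS_c/df_k(x, y)` (a plain sum, not a spatial mean; the two
#' differ only by the constant map area, which later min-max normalization
#' removes).
#'
#' @param grads `h_f x w_f x K` array (or list of K matrices) of class-score
#'   gradients, as from [class_score_gradients()].
#' @return Numeric vector of K weights.
#' @export
gradient_weights <- function(grads) {
  g <- as_map_array(grads, "grads")
  if (dim(g)[3] < 1L) stop("no gradient maps supplied", call. = FALSE)
  apply(g, 3L, sum)
}

#' Shannon entropy of a feature map (bits)
#'
#' The real-valued map is min-max scaled to `[0, 255]` and rounded to
#' integers, giving a 256-symbol distribution whose entropy
#' `H = -sum p_n log2 p_n` is returned. A constant map (zero range) carries
#' no information and returns 0 bits.
#'
#' @param feature_map numeric matrix.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
feature_entropy <- function(feature_map) {
  v <- as.vector(feature_map)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("feature map contains non-finite values", call. = FALSE)
  }
  rng <- max(v) - min(v)
  if (rng == 0) return(0)
  q <- round((v - min(v)) / rng * 255)
  p <- tabulate(q + 1L, nbins = 256L) / length(q)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy profile and gating of a feature stack
#'
#' Computes per-map entropies and the kept-map set for a gating mode:
#' `"all"` keeps every map; `"positive"` keeps maps with `H > 0`;
#' `"top_mass"` ranks maps by descending entropy and keeps the smallest
#' prefix whose cumulative entropy reaches `p` of the total (default 0.95),
#' never keeping zero-entropy maps.
#'
#' @param features a `feature_stack`, `h_f x w_f x K` array or list of maps.
#' @param mode gating mode: `"all"`, `"positive"` or `"top_mass"`.
#' @param p cumulative entropy mass for `"top_mass"`.
#' @return An object of class `entropy_profile`: list with `H` (bits per
#'   map), `mode`, `p` and the `kept` index set.
#' @export
entropy_profile <- function(features, mode = c("all", "positive", "top_mass"),
                            p = 0.95) {
  mode <- match.arg(mode)
  maps <- if (inherits(features, "feature_stack")) features$maps
          else as_map_array(features)
  H <- apply(maps, 3L, feature_entropy)
  kept <- switch(mode,
    all = seq_along(H),
    positive = which(H > 0),
    top_mass = {
      if (sum(H) == 0) {
        integer(0)
      } else {
        ord <- order(H, decreasing = TRUE)
        ord <- ord[H[ord] > 0]
        n_keep <- which(cumsum(H[ord]) >= p * sum(H) - 1e-12)[1]
        sort(ord[seq_len(n_keep)])
      }
    })
  structure(list(H = H, mode = mode, p = if (mode == "top_mass") p else NA_real_,
                 kept = kept),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile: mode '%s', %d/%d maps kept, H in [%.2f, %.2f] bits>\n",
              x$mode, length(x$kept), length(x$H), min(x$H), max(x$H)))
  invisible(x)
}

#' Fraction of feature maps utilized by a gating rule
#'
#' @param profile an [entropy_profile()].
#' @return `|kept| / K`, in `[0, 1]`.
#' @export
featuremap_usage <- function(profile) {
  stopifnot(inherits(profile, "entropy_profile"))
  length(profile$kept) / length(profile$H)
}

#' Raw EGrad-CAM heatmap
#'
#' `M = ReLU(sum over kept maps of alpha_k * f_k)`: a rectified weighted sum
#' of the entropy-kept feature maps, with gradient weights from
#' [gradient_weights()]. Maps outside the kept set are frozen (contribute
#' nothing). An empty kept set yields an all-zero map with a warning.
#'
#' @inheritParams entropy_profile
#' @param grads gradients aligned with `features` (array or list of maps).
#' @return Raw heatmap matrix (`h_f x w_f`, nonnegative) with the
#'   [entropy_profile()] attached as attribute `"profile"`.
#' @export
egrad_cam <- function(features, grads, mode = c("all", "positive", "top_mass"),
                      p = 0.95) {
  mode <- match.arg(mode)
  maps <- if (inherits(features, "feature_stack")) features$maps
          else as_map_array(features)
  g <- as_map_array(grads, "grads")
  stopifnot(all(dim(maps) == dim(g)))
  alpha <- gradient_weights(g)
  profile <- entropy_profile(maps, mode = mode, p = p)
  raw <- matrix(0, dim(maps)[1], dim(maps)[2])
  if (length(profile$kept) == 0) {
    warning("entropy gating kept no feature maps; heatmap is all zero",
            call. = FALSE)
  } else {
    for (k in profile$kept) raw <- raw + alpha[k] * maps[, , k]
    raw <- pmax(raw, 0)
  }
  attr(raw, "profile") <- profile
  attr(raw, "alpha") <- alpha
  raw
}

#' Ablation importance of one feature map
#'
#' `beta_k = (S_c - S_c^k) / S_c`, the relative drop in the pre-softmax
#' class score when feature map `k` is removed. Undefined when `S_c` is
#' (numerically) zero.
#'
#' @inheritParams backend-contract
#' @param tol magnitude below which `S_c` is treated as zero.
#' @return The scalar importance `beta_k`.
#' @export
ablation_importance <- function(backend, image, class, k, tol = 1e-8) {
  fs <- forward_with_features(backend, image)
  s_c <- unname(fs$pre_softmax[class])
  if (abs(s_c) < tol) {
    stop("undefined importance at zero class score", call. = FALSE)
  }
  (s_c - score_with_ablated_map(backend, image, class, k)) / s_c
}

#' Raw Ablation-CAM heatmap
#'
#' `M = ReLU(sum_k beta_k * F_k)` with one ablated forward pass per feature
#' map.
#'
#' @inheritParams backend-contract
#' @param tol passed to the zero-score guard of [ablation_importance()].
#' @return Raw heatmap matrix with attributes `"beta"` (the K importances)
#'   and `"ablated_scores"` (the K ablated pre-softmax scores).
#' @export
ablation_cam <- function(backend, image, class, tol = 1e-8) {
  fs <- forward_with_features(backend, image)
  s_c <- unname(fs$pre_softmax[class])
  if (abs(s_c) < tol) {
    stop("undefined importance at zero class score", call. = FALSE)
  }
  K <- dim(fs$maps)[3]
  ablated <- vapply(seq_len(K), function(k)
    unname(score_with_ablated_map(backend, image, class, k)), numeric(1))
  beta <- (s_c - ablated) / s_c
  raw <- matrix(0, dim(fs$maps)[1], dim(fs$maps)[2])
  for (k in seq_len(K)) raw <- raw + beta[k] * fs$maps[, , k]
  raw <- pmax(raw, 0)
  attr(raw, "beta") <- beta
  attr(raw, "ablated_scores") <- ablated
  raw
}

#' Post-process a raw heatmap to input resolution
#'
#' Bilinear upsampling to the classifier input resolution followed by
#' min-max normalization to `[0, 1]`. All-zero and constant maps carry no
#' discriminative signal and normalize to all-zero.
#'
#' @param raw nonnegative raw heatmap matrix (post-ReLU).
#' @param target_shape `c(rows, cols)` of the classifier input.
#' @param method heatmap method tag.
#' @param class explained class label.
#' @param entropy_mode text tag recording the gating rule applied.
#' @return An object of class `heatmap`: list with the `values` matrix in
#'   `[0, 1]`, `method`, `class` and `entropy_mode`.
#' @export
postprocess_heatmap <- function(raw, target_shape,
                                method = "egrad_cam", class = NA_character_,
                                entropy_mode = "none") {
  stopifnot(min(raw) >= 0)
  if (length(target_shape) == 1L) target_shape <- c(target_shape, target_shape)
  up <- resample_matrix(unclass(raw), target_shape, "bilinear")
  up <- pmax(up, 0)
  rng <- max(up) - min(up)
  values <- if (rng == 0) matrix(0, target_shape[1], target_shape[2])
            else (up - min(up)) / rng
  new_heatmap(values, method = method, class = class,
              entropy_mode = entropy_mode)
}

new_heatmap <- function(values, method, class, entropy_mode = "none") {
  method <- check_vocab(method, HEATMAP_METHODS, "method")
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    stop("heatmap values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values, method = method, class = class,
                 entropy_mode = entropy_mode),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap %s (%s) for class '%s', %d x %d, max %.3f>\n",
              x$method, x$entropy_mode, x$class,
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Generate a post-processed heatmap for one image
#'
#' Backend-dispatched heatmap generation: learned backends run the requested
#' CAM method; [oracle_backend()]s return their planted annotation-driven
#' map. This is the entry point used by [run_contribution_analysis()] and
#' [evaluate_faithfulness()].
#'
#' @inheritParams backend-contract
#' @param annotation the image's [lesion_annotation()] (RoI frame); needed
#'   by oracle backends.
#' @param class explained class; defaults to the backend's predicted class.
#' @param method `"egrad_cam"`, `"ablation_cam"` or `"grad_cam"` (classical
#'   Grad-CAM, i.e. ungated EGrad-CAM tagged as such).
#' @param gate entropy gating mode for EGrad-CAM.
#' @param p cumulative entropy mass for `gate = "top_mass"`.
#' @return A `heatmap` at input resolution; for EGrad-CAM the feature-map
#'   usage fraction is attached as attribute `"usage"`.
#' @export
generate_heatmap <- function(backend, image, annotation = NULL, class = NULL,
                             method = c("egrad_cam", "ablation_cam", "grad_cam"),
                             gate = c("all", "positive", "top_mass"),
                             p = 0.95, ...) {
  UseMethod("generate_heatmap")
}

#' @rdname generate_heatmap
#' @export
generate_heatmap.tiny_cnn <- function(backend, image, annotation = NULL,
                                      class = NULL,
                                      method = c("egrad_cam", "ablation_cam",
                                                 "grad_cam"),
                                      gate = c("all", "positive", "top_mass"),
                                      p = 0.95, ...) {
  method <- match.arg(method)
  gate <- match.arg(gate)
  if (is.null(class)) class <- predict_class(backend, image)$class
  shape <- input_shape(backend)
  if (method == "ablation_cam") {
    raw <- ablation_cam(backend, image, class)
    hm <- postprocess_heatmap(raw, shape, method, class, "none")
    attr(hm, "beta") <- attr(raw, "beta")
    return(hm)
  }
  fs <- forward_with_features(backend, image)
  grads <- class_score_gradients(backend, image, class)
  use_gate <- if (method == "grad_cam") "all" else gate
  raw <- egrad_cam(fs, grads, mode = use_gate, p = p)
  tag <- if (use_gate == "top_mass") sprintf("top_mass(%g)", p) else use_gate
  hm <- postprocess_heatmap(raw, shape, method, class, tag)
  attr(hm, "usage") <- featuremap_usage(attr(raw, "profile"))
  hm
}
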