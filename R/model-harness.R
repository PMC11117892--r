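#' @title Classifier backend contract and the tiny CNN
#' @name model-harness
#' @description
#' The class-activation methods only need four things from a classifier: a
#' forward pass exposing the activations of one designated convolutional
#' layer together with the pre-softmax class scores
#' ([forward_with_features()]), the gradients of a class score with respect
#' to those activations ([class_score_gradients()]), the class score
#' obtained when one feature map is zeroed and the downstream computation
#' re-run ([score_with_ablated_map()]), and the input geometry
#' ([input_shape()], [n_classes()]). Any object implementing these generics
#' can drive the explanation pipeline; the package ships a small from-scratch
#' CNN ([build_tiny_cnn()]) so the framework runs without pretrained weights,
#' plus an annotation-driven oracle backend ([oracle_backend()]) for exact
#' recovery tests.
NULL

#' Backend contract generics
#'
#' @param backend a classifier backend.
#' @param image a [gs_image()] or intensity matrix at the backend's input
#'   size, on the `[0, 255]` scale.
#' @param class class label (`"benign"` or `"malignant"`) whose score is
#'   explained.
#' @param k feature-map index.
#' @param ... passed to methods.
#' @return `forward_with_features()` a `feature_stack` (list with `maps`, an
#'   `h_f x w_f x K` array, `layer_name` and the named `pre_softmax` score
#'   vector); `class_score_gradients()` an `h_f x w_f x K` array of
#'   `dS_c/df_k(x, y)`; `score_with_ablated_map()` a single pre-softmax
#'   score; `input_shape()` `c(rows, cols)`; `n_classes()` an integer.
#' @name backend-contract
NULL

#' @rdname backend-contract
#' @export
forward_with_features <- function(backend, image, ...) {
  UseMethod("forward_with_features")
}

#' @rdname backend-contract
#' @export
class_score_gradients <- function(backend, image, class, ...) {
  UseMethod("class_score_gradients")
}

#' @rdname backend-contract
#' @export
score_with_ablated_map <- function(backend, image, class, k, ...) {
  UseMethod("score_with_ablated_map")
}

#' @rdname backend-contract
#' @export
input_shape <- function(backend) UseMethod("input_shape")

#' @rdname backend-contract
#' @export
n_classes <- function(backend) UseMethod("n_classes")

#' Predict the class of one image
#'
#' @inheritParams backend-contract
#' @param annotation the image's [lesion_annotation()]; ignored by learned
#'   backends, required by [oracle_backend()]s whose prediction rule reads
#'   the ground truth.
#' @return A list with `class`, `confidence` (post-softmax probability of
#'   the predicted class) and the named `pre_softmax` vector.
#' @export
predict_class <- function(backend, image, annotation = NULL, ...) {
  UseMethod("predict_class")
}

#' Build the tiny from-scratch CNN backend
#'
#' A minimal convolutional classifier mirroring the GAP topology that
#' class-activation mapping assumes: `n_blocks` blocks of 3x3 convolution
#' (stride 1, zero padding) and ReLU, with 2x2 average pooling between
#' blocks, followed by global average pooling over the last activation and a
#' linear two-class head. The designated explanation layer is the last
#' convolutional (post-ReLU) activation. Weights are He-initialized from the
#' seed, so two builds with the same arguments are identical.
#'
#' @param n_blocks number of convolution blocks (>= 1).
#' @param n_maps feature maps per convolution (>= 2).
#' @param input_size classifier input size, scalar or `c(rows, cols)`; must
#'   be divisible by `2^(n_blocks - 1)` with at least 2 pixels left.
#' @param seed integer seed for weight initialization.
#' @return An object of class `tiny_cnn` implementing the backend contract.
#' @export
build_tiny_cnn <- function(n_blocks = 3L, n_maps = 8L, input_size = 32L,
                           seed = 1L) {
  stopifnot(n_blocks >= 1L, n_maps >= 2L)
  if (length(input_size) == 1L) input_size <- c(input_size, input_size)
  input_size <- as.integer(input_size)
  div <- 2L^(n_blocks - 1L)
  if (any(input_size %% div != 0L) || any(input_size %/% div < 2L)) {
    stop("input size ", paste(input_size, collapse = "x"),
         " too small for ", n_blocks, " blocks of pooling", call. = FALSE)
  }
  with_seed_(seed, {
    conv <- vector("list", n_blocks)
    idx <- vector("list", n_blocks)
    h <- input_size[1]; w <- input_size[2]
    cin <- 1L
    for (b in seq_len(n_blocks)) {
      conv[[b]] <- list(
        W = matrix(rnorm(9L * cin * n_maps, sd = sqrt(2 / (9 * cin))),
                   9L * cin, n_maps),
        b = numeric(n_maps))
      idx[[b]] <- im2col_indices(h, w, cin)
      cin <- n_maps
      if (b < n_blocks) { h <- h %/% 2L; w <- w %/% 2L }
    }
    head_W <- matrix(rnorm(n_maps * 2L, sd = sqrt(1 / n_maps)), n_maps, 2L,
                     dimnames = list(NULL, CLASS_LEVELS))
    structure(list(input_shape = input_size, n_blocks = n_blocks,
                   n_maps = n_maps, seed = seed, classes = CLASS_LEVELS,
                   conv = conv, idx = idx,
                   head = list(W = head_W, b = setNames(numeric(2L),
                                                        CLASS_LEVELS)),
                   layer_name = sprintf("conv%d_relu", n_blocks)),
              class = "tiny_cnn")
  })
}

#' @export
print.tiny_cnn <- function(x, ...) {
  cat(sprintf(
    "<tiny_cnn: %d block(s), %d maps, input %dx%d, layer '%s', seed %d>\n",
    x$n_blocks, x$n_maps, x$input_shape[1], x$input_shape[2],
    x$layer_name, x$seed))
  invisible(x)
}

check_input <- function(backend, px) {
  if (!all(dim(px) == backend$input_shape)) {
    stop(sprintf("image is %dx%d but the backend expects %dx%d (prepare the RoI first)",
                 nrow(px), ncol(px),
                 backend$input_shape[1], backend$input_shape[2]),
         call. = FALSE)
  }
  px
}

#' @rdname backend-contract
#' @export
forward_with_features.tiny_cnn <- function(backend, image, ...) {
  px <- check_input(backend, as_pixels(image))
  fw <- cnn_forward(backend, px)
  structure(list(maps = fw$features, layer_name = backend$layer_name,
                 pre_softmax = fw$scores),
            class = "feature_stack")
}

#' @rdname backend-contract
#' @export
class_score_gradients.tiny_cnn <- function(backend, image, class, ...) {
  class <- check_vocab(class, backend$classes, "class")
  px <- check_input(backend, as_pixels(image))
  fw <- cnn_forward(backend, px)
  d <- dim(fw$features)
  # S_c = sum_k w_ck * mean(F_k) + b_c, so dS_c/df_k(x, y) = w_ck / (h*w)
  w <- backend$head$W[, class] / (d[1] * d[2])
  array(rep(w, each = d[1] * d[2]), d)
}

#' @rdname backend-contract
#' @export
score_with_ablated_map.tiny_cnn <- function(backend, image, class, k, ...) {
  class <- check_vocab(class, backend$classes, "class")
  px <- check_input(backend, as_pixels(image))
  fw <- cnn_forward(backend, px)
  stopifnot(k >= 1L, k <= backend$n_maps)
  maps <- fw$features
  maps[, , k] <- 0                       # remove map k, re-run downstream
  unname(rescore_features(backend, maps)[class])
}

# Re-run the GAP + linear head on a (possibly modified) feature stack.
rescore_features <- function(backend, maps) {
  s <- apply(maps, 3L, mean)
  scores <- drop(s %*% backend$head$W) + backend$head$b
  names(scores) <- backend$classes
  scores
}

#' Linear-head weights of the tiny CNN
#'
#' Exposes the GAP head so closed-form identities (ablating map `k` changes
#' `S_c` by exactly `w_ck * mean(F_k)`) can be checked externally.
#'
#' @param backend a `tiny_cnn`.
#' @return List with `W` (`K x 2` matrix, columns named by class) and `b`.
#' @export
head_weights <- function(backend) {
  stopifnot(inherits(backend, "tiny_cnn"))
  backend$head
}

#' @rdname backend-contract
#' @export
input_shape.tiny_cnn <- function(backend) backend$input_shape

#' @rdname backend-contract
#' @export
n_classes.tiny_cnn <- function(backend) 2L

#' @rdname predict_class
#' @export
predict_class.tiny_cnn <- function(backend, image, annotation = NULL, ...) {
  px <- check_input(backend, as_pixels(image))
  fw <- cnn_forward(backend, px)
  p <- softmax(fw$scores)
  i <- which.max(fw$scores)
  list(class = backend$classes[i], confidence = unname(p[i]),
       pre_softmax = fw$scores)
}

#' Confidence of a backend in a given class
#'
#' Post-softmax probability assigned to `class` for `image`; used by the
#' faithfulness metrics, which compare confidences on original images and on
#' their explanation maps.
#'
#' @inheritParams backend-contract
#' @export
class_confidence <- function(backend, image, class) {
  fs <- forward_with_features(backend, image)
  unname(softmax(fs$pre_softmax)[class])
}

#' Train the tiny CNN backend
#'
#' Minibatch Adam on the softmax cross-entropy, fully deterministic given the
#' seed (seeded initialization is part of the backend; seeded shuffling is
#' part of training). The per-class metrics follow the usual definitions
#' with malignant as the positive class: TNR = TN / (TN + FP),
#' TPR = TP / (TP + FN).
#'
#' @param backend a `tiny_cnn` (its weights are the starting point).
#' @param dataset tibble with list-columns `image` (RoI-frame [gs_image()]s
#'   at the backend's input size) and either a `class` column or an
#'   `annotation` list-column carrying the class; at least 2 images per
#'   class.
#' @param epochs passes over the data; `0` returns the backend unchanged.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling shuffling.
#' @param restarts number of random restarts; when greater than 1, the
#'   network is re-initialized and re-trained with seeds derived from
#'   `seed` and the fit with the highest training accuracy is kept
#'   (deterministic model selection on training data only). Useful because
#'   optimization of a net this small is initialization-sensitive.
#' @return An object of class `tiny_cnn_fit`: list with the trained
#'   `backend`, a one-row `metrics` tibble (training accuracy, TNR, TPR) and
#'   a per-epoch `history` tibble.
#' @export
train_backend <- function(backend, dataset, epochs = 30L, lr = 5e-3,
                          batch_size = 8L, seed = 1L, restarts = 1L) {
  stopifnot(inherits(backend, "tiny_cnn"))
  if (restarts > 1L) {
    fits <- lapply(seq_len(restarts) - 1L, function(r) {
      s <- seed + 1000L * r
      train_backend(build_tiny_cnn(backend$n_blocks, backend$n_maps,
                                   backend$input_shape, seed = s),
                    dataset, epochs = epochs, lr = lr,
                    batch_size = batch_size, seed = s)
    })
    acc <- vapply(fits, function(f) f$metrics$accuracy, numeric(1))
    return(fits[[which.max(acc)]])
  }
  imgs <- purrr::map(dataset$image, as_pixels)
  labels <- dataset_classes(dataset)
  if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
    stop("training needs at least 2 images of each class", call. = FALSE)
  }
  purrr::walk(imgs, ~check_input(backend, .x))
  label_idx <- match(labels, backend$classes)
  n <- length(imgs)
  model <- backend
  history <- vector("list", epochs)
  if (epochs > 0L) {
    state <- adam_init(model)
    for (ep in seq_len(epochs)) {
      order <- with_seed_(seed + ep, sample.int(n))
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        batch <- order[start:min(start + batch_size - 1L, n)]
        acc <- NULL
        bl <- 0
        for (i in batch) {
          fw <- cnn_forward(model, imgs[[i]], keep_cache = TRUE)
          bw <- cnn_backward(model, fw, label_idx[i])
          acc <- sum_grads(acc, bw$grads)
          bl <- bl + bw$loss
        }
        acc <- scale_grads(acc, 1 / length(batch))
        st <- adam_step(model, acc, state, lr)
        model <- st$model; state <- st$state
        losses <- c(losses, bl / length(batch))
      }
      history[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses))
    }
  }
  preds <- purrr::map_chr(imgs, ~predict_class(model, .x)$class)
  metrics <- classification_metrics(labels, preds)
  structure(list(backend = model, metrics = metrics,
                 history = dplyr::bind_rows(history)),
            class = "tiny_cnn_fit")
}

dataset_classes <- function(dataset) {
  if ("class" %in% names(dataset)) {
    as.character(dataset$class)
  } else if ("annotation" %in% names(dataset)) {
    purrr::map_chr(dataset$annotation, "class")
  } else {
    stop("dataset needs a 'class' column or an 'annotation' list-column",
         call. = FALSE)
  }
}

#' Accuracy, TNR and TPR of predictions
#'
#' @param true_class,predicted_class class label vectors.
#' @return One-row tibble with `n`, `accuracy`, `tnr`, `tpr`.
#' @export
classification_metrics <- function(true_class, predicted_class) {
  oc <- outcome_of(true_class, predicted_class)
  tn <- sum(oc == "TN"); tp <- sum(oc == "TP")
  fp <- sum(oc == "FP"); fn <- sum(oc == "FN")
  tibble::tibble(
    n = length(oc),
    accuracy = (tn + tp) / length(oc),
    tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' @export
print.tiny_cnn_fit <- function(x, ...) {
  cat("<tiny_cnn_fit>\n")
  print(x$backend)
  cat(sprintf("  training accuracy %.3f (TNR %.3f, TPR %.3f) on %d images\n",
              x$metrics$accuracy, x$metrics$tnr, x$metrics$tpr, x$metrics$n))
  invisible(x)
}
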