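test_that("tiny CNN builds are deterministic and honor the shape contract", {
  img <- withr::with_seed(4, matrix(runif(32 * 32, 0, 255), 32, 32))
  a <- build_tiny_cnn(n_blocks = 2, n_maps = 8, input_size = 32, seed = 5)
  b <- build_tiny_cnn(n_blocks = 2, n_maps = 8, input_size = 32, seed = 5)
  fa <- forward_with_features(a, img)
  fb <- forward_with_features(b, img)
  expect_identical(fa$pre_softmax, fb$pre_softmax)
  expect_equal(dim(fa$maps)[3], 8)
  expect_equal(length(fa$pre_softmax), 2)
  expect_named(fa$pre_softmax, c("benign", "malignant"))

  c8 <- build_tiny_cnn(n_blocks = 1, n_maps = 8, input_size = c(32, 32))
  expect_equal(dim(forward_with_features(c8, img)$maps), c(32, 32, 8))
  expect_error(build_tiny_cnn(n_blocks = 5, input_size = 16), "too small")
  expect_error(forward_with_features(a, matrix(0, 16, 16)), "expects 32x32")
})

test_that("ablated scores match a brute-force re-forward for every map", {
  withr::with_seed(21, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 6, input_size = 16, seed = 3)
    img <- matrix(runif(256, 0, 255), 16, 16)
    fs <- forward_with_features(cnn, img)
    hw <- head_weights(cnn)
    for (k in 1:6) {
      maps <- fs$maps
      maps[, , k] <- 0
      s <- apply(maps, 3, mean)
      brute <- drop(s %*% hw$W) + hw$b   # GAP + linear head by hand
      for (cl in c("benign", "malignant")) {
        expect_equal(score_with_ablated_map(cnn, img, cl, k),
                     unname(brute[cl]), tolerance = 1e-12)
      }
    }
  })
})

test_that("ablation matches the GAP linear-head closed form", {
  withr::with_seed(22, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 6, input_size = 16, seed = 9)
    img <- matrix(runif(256, 0, 255), 16, 16)
    fs <- forward_with_features(cnn, img)
    hw <- head_weights(cnn)
    for (k in 1:6) {
      drop_k <- fs$pre_softmax["malignant"] -
        score_with_ablated_map(cnn, img, "malignant", k)
      expect_equal(unname(drop_k),
                   unname(hw$W[k, "malignant"]) * mean(fs$maps[, , k]),
                   tolerance = 1e-12)
    }
  })
})

test_that("class score gradients match central finite differences", {
  withr::with_seed(23, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 4, input_size = 16, seed = 2)
    img <- matrix(runif(256, 0, 255), 16, 16)
    fs <- forward_with_features(cnn, img)
    g <- class_score_gradients(cnn, img, "benign")
    hw <- head_weights(cnn)
    score_of <- function(maps) {
      sum(apply(maps, 3, mean) * hw$W[, "benign"]) + hw$b[["benign"]]
    }
    eps <- 1e-4
    for (t in 1:5) {
      i <- sample(dim(fs$maps)[1], 1); j <- sample(dim(fs$maps)[2], 1)
      k <- sample(dim(fs$maps)[3], 1)
      up <- fs$maps; up[i, j, k] <- up[i, j, k] + eps
      dn <- fs$maps; dn[i, j, k] <- dn[i, j, k] - eps
      fd <- (score_of(up) - score_of(dn)) / (2 * eps)
      expect_equal(g[i, j, k], unname(fd), tolerance = 1e-3)
    }
  })
})

test_that("metric definitions and training-loop edge cases hold", {
  # hand-made confusion: TN=8, FP=2, FN=1, TP=9
  truth <- c(rep("benign", 10), rep("malignant", 10))
  pred <- c(rep("benign", 8), rep("malignant", 2),
            rep("benign", 1), rep("malignant", 9))
  m <- classification_metrics(truth, pred)
  expect_equal(m$tnr, 0.8)
  expect_equal(m$tpr, 0.9)
  expect_equal(m$accuracy, 0.85)

  ds <- make_roi_dataset(6, size = 16, seed = 31)
  cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 4, input_size = 16, seed = 1)
  fit0 <- train_backend(cnn, ds, epochs = 0, seed = 1)
  expect_identical(fit0$backend$conv, cnn$conv)
  expect_identical(fit0$backend$head, cnn$head)

  single <- ds[ds$class == ds$class[1], ]
  expect_error(train_backend(cnn, single, epochs = 1), "each class")
})

test_that("training separates the synthetic classes", {
  train <- make_roi_dataset(200, size = 32, seed = 7)
  test <- make_roi_dataset(50, size = 32, seed = 8)
  cnn <- build_tiny_cnn(seed = 1)
  fit <- train_backend(cnn, train, epochs = 30, seed = 1)
  expect_gte(fit$metrics$accuracy, 0.9)
  preds <- vapply(test$image, function(im) predict_class(fit$backend, im)$class,
                  character(1))
  held_out <- classification_metrics(test$class, preds)
  expect_gt(held_out$accuracy, 0.8)
  # training twice with the same seed is bit-identical
  fit2 <- train_backend(cnn, train, epochs = 2, seed = 4)
  fit3 <- train_backend(cnn, train, epochs = 2, seed = 4)
  expect_identical(fit2$backend$head, fit3$backend$head)
})
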