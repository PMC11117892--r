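test_that("gradient weights are plain spatial sums", {
  expect_equal(gradient_weights(matrix(1, 3, 3)), 9)
  expect_equal(gradient_weights(matrix(0, 5, 5)), 0)
  withr::with_seed(1, {
    g <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    brute <- numeric(3)
    for (k in 1:3) for (x in 1:4) for (y in 1:4) {
      brute[k] <- brute[k] + g[x, y, k]
    }
    expect_equal(gradient_weights(g), brute)
  })
  expect_error(gradient_weights(array(0, c(2, 2, 0))), "no gradient maps")
})

test_that("feature entropy reproduces exact reference distributions", {
  expect_equal(feature_entropy(matrix(3.7, 9, 9)), 0)
  uniform256 <- matrix(rep(0:255, each = 1), 16, 16)
  expect_equal(feature_entropy(uniform256), 8)
  half <- matrix(c(rep(0, 50), rep(1, 50)), 10, 10)
  expect_equal(feature_entropy(half), 1)
  expect_error(feature_entropy(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("entropy gating modes keep the promised map sets", {
  withr::with_seed(8, {
    maps <- array(0, c(6, 6, 5))
    maps[, , 1] <- rnorm(36)
    maps[, , 2] <- rnorm(36)
    maps[, , 3] <- 7          # constant: zero entropy
    maps[, , 4] <- rnorm(36)
    maps[, , 5] <- 0          # constant
    all_mode <- entropy_profile(maps, "all")
    expect_equal(all_mode$kept, 1:5)
    expect_equal(featuremap_usage(all_mode), 1)
    pos <- entropy_profile(maps, "positive")
    expect_equal(pos$kept, c(1, 2, 4))
    expect_equal(featuremap_usage(pos), 0.6)
    # top-mass kept sets are nested in p
    ps <- c(0.3, 0.6, 0.9, 0.99)
    kept <- lapply(ps, function(p) entropy_profile(maps, "top_mass", p)$kept)
    for (i in seq_len(length(ps) - 1)) {
      expect_true(all(kept[[i]] %in% kept[[i + 1]]))
    }
    # all-constant stack keeps nothing under entropy gating
    flat <- array(2, c(4, 4, 3))
    expect_equal(entropy_profile(flat, "positive")$kept, integer(0))
    expect_equal(featuremap_usage(entropy_profile(flat, "positive")), 0)
  })
})

test_that("egrad_cam single-map, sign and empty-gate behavior", {
  f <- matrix(abs(rnorm(16)), 4, 4)
  g <- matrix(1 / 16, 4, 4)   # alpha = 1
  raw <- egrad_cam(array(f, c(4, 4, 1)), array(g, c(4, 4, 1)), "all")
  expect_equal(unclass(raw), f, ignore_attr = TRUE)

  gneg <- array(-1, c(4, 4, 2))
  fpos <- array(abs(rnorm(32)), c(4, 4, 2))
  raw2 <- egrad_cam(fpos, gneg, "all")
  expect_true(all(raw2 == 0))

  flat <- array(1, c(4, 4, 2))
  expect_warning(raw3 <- egrad_cam(flat, gneg, "positive"), "no feature maps")
  expect_true(all(raw3 == 0))
})

test_that("ungated egrad_cam equals an independent Grad-CAM after normalization", {
  withr::with_seed(17, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 8, input_size = 16, seed = 6)
    for (i in 1:5) {
      img <- matrix(runif(256, 0, 255), 16, 16)
      cls <- predict_class(cnn, img)$class
      fs <- forward_with_features(cnn, img)
      grads <- class_score_gradients(cnn, img, cls)
      mine <- minmax01(unclass(egrad_cam(fs, grads, "all")))
      ref <- reference_gradcam(fs$maps, grads)
      expect_lt(max(abs(mine - ref)), 1e-6)
    }
  })
})

test_that("ablation importances follow their definition and guard zero scores", {
  withr::with_seed(18, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 6, input_size = 16, seed = 2)
    img <- matrix(runif(256, 0, 255), 16, 16)
    fs <- forward_with_features(cnn, img)
    hw <- head_weights(cnn)
    s_c <- unname(fs$pre_softmax["malignant"])
    for (k in 1:6) {
      beta <- ablation_importance(cnn, img, "malignant", k)
      expect_equal(beta,
                   unname(hw$W[k, "malignant"]) * mean(fs$maps[, , k]) / s_c,
                   tolerance = 1e-10)
    }
    # zero class score: force the head to produce S_c = 0
    dead <- cnn
    dead$head$W[, "benign"] <- 0
    dead$head$b["benign"] <- 0
    expect_error(ablation_importance(dead, img, "benign", 1), "zero")
    expect_error(ablation_cam(dead, img, "benign"), "zero")
  })
})

test_that("ablation_cam equals the rectified beta-weighted sum of maps", {
  withr::with_seed(19, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 5, input_size = 16, seed = 4)
    img <- matrix(runif(256, 0, 255), 16, 16)
    raw <- ablation_cam(cnn, img, "benign")
    fs <- forward_with_features(cnn, img)
    s_c <- unname(fs$pre_softmax["benign"])
    brute_scores <- vapply(1:5, function(k) {
      maps <- fs$maps; maps[, , k] <- 0
      unname(camlink:::rescore_features(cnn, maps)["benign"])
    }, numeric(1))
    expect_identical(attr(raw, "ablated_scores"), brute_scores)
    beta <- (s_c - brute_scores) / s_c
    m <- matrix(0, dim(fs$maps)[1], dim(fs$maps)[2])
    for (k in 1:5) m <- m + beta[k] * fs$maps[, , k]
    expect_equal(unclass(raw), pmax(m, 0), ignore_attr = TRUE)
  })
})

test_that("postprocessing normalizes, preserves zeros and flattens constants", {
  raw <- matrix(c(0, 1, 2, 4), 2, 2)
  hm <- postprocess_heatmap(raw, c(8, 8), "grad_cam", "benign")
  expect_s3_class(hm, "heatmap")
  expect_equal(max(hm$values), 1)
  expect_equal(min(hm$values), 0)
  expect_equal(dim(hm$values), c(8, 8))

  zero <- postprocess_heatmap(matrix(0, 4, 4), c(8, 8))
  expect_true(all(zero$values == 0))
  const <- postprocess_heatmap(matrix(2.5, 4, 4), c(8, 8))
  expect_true(all(const$values == 0))
  expect_error(postprocess_heatmap(matrix(-1, 4, 4), c(8, 8)))
})

test_that("generated heatmaps always lie in [0,1] and peak at 1 when informative", {
  withr::with_seed(20, {
    cnn <- build_tiny_cnn(n_blocks = 2, n_maps = 8, input_size = 16, seed = 3)
    for (i in 1:8) {
      img <- matrix(runif(256, 0, 255), 16, 16)
      for (m in c("egrad_cam", "ablation_cam", "grad_cam")) {
        hm <- generate_heatmap(cnn, img, method = m, gate = "top_mass")
        expect_gte(min(hm$values), 0)
        expect_lte(max(hm$values), 1)
        expect_true(max(hm$values) %in% c(0, 1))
      }
    }
  })
})
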