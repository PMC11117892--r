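test_that("significant ratio counts region pixels at or above threshold", {
  hv <- matrix(c(0.5, 0.6, 0.4, 0.1), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  expect_equal(significant_ratio(hv, mask), 0.5)
  expect_equal(significant_ratio(matrix(0.9, 3, 3), matrix(TRUE, 3, 3)), 1)
  expect_error(significant_ratio(hv, matrix(FALSE, 2, 2)),
               "no annotated pixels")

  withr::with_seed(51, {
    for (i in 1:100) {
      hv <- matrix(runif(400), 20, 20)
      mask <- matrix(runif(400) < 0.3, 20, 20)
      if (!any(mask)) next
      brute <- 0; tot <- 0
      for (r in 1:20) for (c in 1:20) {
        if (mask[r, c]) {
          tot <- tot + 1
          if (hv[r, c] >= 0.5) brute <- brute + 1
        }
      }
      expect_identical(significant_ratio(hv, mask), brute / tot)
    }
  })
})

test_that("average ratio is the mean, with empty groups reported absent", {
  expect_equal(average_ratio(c(0.2, 0.4)), 0.3)
  expect_equal(average_ratio(0.77), 0.77)
  expect_true(is.na(average_ratio(numeric(0))))
  withr::with_seed(52, {
    r <- runif(1000)
    av <- average_ratio(r)
    expect_gte(av, min(r)); expect_lte(av, max(r))
  })
})

test_that("contribution categories follow the graded bounds exactly", {
  expect_equal(as.character(categorize(0.38)), "Medium")
  expect_equal(as.character(categorize(0.16)), "Very Low")
  expect_equal(as.character(categorize(0.31)), "Low")
  expect_equal(as.character(categorize(c(0, 0.2, 0.35, 0.5))),
               c("No", "Very Low", "Low", "High"))
  expect_true(is.na(categorize(NA_real_)))
  expect_error(categorize(1.2), "\\[0, 1\\]")
  # monotone over the ordered levels
  withr::with_seed(53, {
    x <- sort(runif(200))
    expect_true(!is.unsorted(categorize(x)))
  })
})

test_that("heatmap aggregation is the pixelwise mean", {
  h1 <- postprocess_heatmap(matrix(0, 4, 4), c(4, 4))
  pat <- matrix(0, 4, 4); pat[1:2, ] <- 4
  h2 <- postprocess_heatmap(pat, c(4, 4))
  agg <- aggregate_heatmaps(list(h1, h2))
  expect_equal(agg$values, h2$values / 2)
  expect_equal(aggregate_heatmaps(list(h2))$values, h2$values)

  withr::with_seed(54, {
    hs <- lapply(1:7, function(i)
      postprocess_heatmap(matrix(runif(16), 4, 4), c(4, 4)))
    brute <- Reduce(`+`, lapply(hs, function(h) h$values)) / 7
    expect_equal(aggregate_heatmaps(hs)$values, brute)
  })
  expect_error(aggregate_heatmaps(list(h1, postprocess_heatmap(matrix(0, 2, 2),
                                                               c(2, 2)))),
               "share one shape")
})

test_that("planted calcification saliency is recovered as High vs No", {
  ds <- prepare_dataset(generate_dataset(16, seed = 61), size = 64)
  hot <- oracle_backend("calcification_hot", prediction = "truth")
  rep_hot <- run_contribution_analysis(ds, hot, method = "egrad_cam",
                                       gate = "all")
  calc <- dplyr::filter(rep_hot$summary, characteristic == "calcification")
  expect_gt(nrow(calc), 0)
  expect_true(all(as.character(calc$category) == "High"))
  expect_true(all(calc$avg_ratio == 1))
  ribbons <- dplyr::filter(rep_hot$summary,
                           characteristic %in% c("shape", "margin"))
  expect_true(all(as.character(ribbons$category) == "No"))

  zero <- oracle_backend("zero", prediction = "truth")
  rep_zero <- run_contribution_analysis(ds, zero)
  expect_true(all(as.character(rep_zero$summary$category) == "No"))
  expect_true(all(rep_zero$summary$avg_ratio == 0))
})

test_that("interior-hot oracle saturates echogenicity and calcification", {
  ds <- prepare_dataset(generate_dataset(10, seed = 62, balance = 0), size = 64)
  backend <- oracle_backend("interior_hot", prediction = "truth")
  rep <- run_contribution_analysis(ds, backend)
  echo <- dplyr::filter(rep$summary, characteristic == "echogenicity")
  expect_true(all(echo$avg_ratio == 1))
  calc <- dplyr::filter(rep$summary, characteristic == "calcification")
  if (nrow(calc) > 0) expect_true(all(calc$avg_ratio == 1))
})

test_that("outcome partition and report bookkeeping are consistent", {
  ds <- prepare_dataset(generate_dataset(12, seed = 63), size = 64)
  # force everything to be predicted malignant: benign cases become FP
  backend <- oracle_backend("interior_hot", prediction = "malignant")
  rep <- run_contribution_analysis(ds, backend)
  expect_setequal(unique(rep$per_image$outcome), c("FP", "TP"))
  for (ch in c("echogenicity", "shape", "margin")) {
    n_ch <- sum(dplyr::filter(rep$summary, characteristic == ch)$n_cases)
    expect_equal(n_ch, nrow(ds))
  }
  n_calc <- sum(dplyr::filter(rep$summary,
                              characteristic == "calcification")$n_cases)
  expect_equal(n_calc, sum(rep$per_image$has_calcification))

  # single correctly classified benign image: only a TN column
  one <- ds[ds$class == "benign", ][1, ]
  rep1 <- run_contribution_analysis(one,
                                    oracle_backend("interior_hot",
                                                   prediction = "truth"))
  expect_equal(unique(rep1$summary$outcome), "TN")
  expect_equal(unique(rep1$per_image$outcome), "TN")
})

test_that("the heatmap explains the predicted class, not the true class", {
  ds <- prepare_dataset(generate_dataset(8, seed = 64), size = 32)
  cnn <- build_tiny_cnn(seed = 2)
  rep <- run_contribution_analysis(ds, cnn, method = "grad_cam")
  expect_equal(nrow(rep$per_image), 8)
  # outcomes derive from (true, predicted) under malignant-positive
  expect_identical(rep$per_image$outcome,
                   outcome_of(rep$per_image$true_class,
                              rep$per_image$predicted_class))
})

test_that("report CSV writing renders absent groups as dashes", {
  ds <- prepare_dataset(generate_dataset(6, seed = 65), size = 64)
  rep <- run_contribution_analysis(ds, oracle_backend("zero",
                                                      prediction = "truth"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, tmp)
  df <- utils::read.csv(tmp, stringsAsFactors = FALSE)
  expect_true(all(c("characteristic", "level", "outcome", "n_cases",
                    "avg_ratio", "category", "featuremap_usage") %in%
                    names(df)))
  expect_true(all(df$featuremap_usage == "-"))  # oracle reports no usage
})
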