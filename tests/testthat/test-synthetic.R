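test_that("label rules follow the planted parameters", {
  spec <- synthetic_spec(amplitude = 0, blur = 0,
                         n_calcifications = c(0, 0), echo = "uniform")
  g <- generate_lesion_image(spec, seed = 1)
  expect_equal(g$annotation$shape, "regular")
  expect_equal(g$annotation$margin, "circumscribed")
  expect_equal(g$annotation$echo, "uniform")
  expect_equal(g$annotation$class, "benign")
  expect_equal(nrow(g$annotation$calcifications), 0)

  spec_m <- synthetic_spec(amplitude = 0.2, blur = 1.5,
                           n_calcifications = c(2, 2), echo = "non_uniform")
  gm <- generate_lesion_image(spec_m, seed = 1)
  expect_equal(gm$annotation$shape, "irregular")
  expect_equal(gm$annotation$margin, "not_circumscribed")
  expect_equal(gm$annotation$class, "malignant")
  expect_equal(nrow(gm$annotation$calcifications), 2)

  expect_error(synthetic_spec(radius = c(50, 70), size = 128), "fit")
  expect_error(synthetic_spec(amplitude = 0.7), "amplitude")
})

test_that("generation is bit-deterministic in the seed", {
  spec <- synthetic_spec(amplitude = 0.25, n_calcifications = c(1, 3))
  a <- generate_lesion_image(spec, seed = 99)
  b <- generate_lesion_image(spec, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotation$boundary, b$annotation$boundary)
  expect_identical(a$annotation$calcifications, b$annotation$calcifications)
  c <- generate_lesion_image(spec, seed = 100)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("the lesion interior is hypoechoic relative to the background", {
  for (s in 1:50) {
    spec <- synthetic_spec(amplitude = if (s %% 2) 0.2 else 0,
                           echo = if (s %% 3) "non_uniform" else "uniform",
                           blur = if (s %% 5) 1.5 else 0)
    g <- generate_lesion_image(spec, seed = s)
    interior <- camlink:::polygon_mask(g$annotation$boundary,
                                       dim(g$image$pixels))
    expect_lt(mean(g$image$pixels[interior]), mean(g$image$pixels[!interior]))
  }
})

test_that("datasets honor the class balance and survive a file round-trip", {
  tmp <- withr::local_tempdir()
  ds <- generate_dataset(10, balance = 0.5, dir = tmp, seed = 5)
  expect_equal(sum(ds$class == "benign"), 5)
  expect_equal(sum(ds$class == "malignant"), 5)
  expect_true(file.exists(file.path(tmp, "index.csv")))
  expect_true(all(file.exists(ds$image_path)))
  expect_true(all(file.exists(ds$annotation_path)))

  back <- read_dataset(tmp)
  expect_equal(back$class, ds$class)
  for (i in 1:10) {
    expect_equal(back$image[[i]]$pixels, ds$image[[i]]$pixels)
    expect_identical(back$annotation[[i]]$boundary,
                     ds$annotation[[i]]$boundary)
  }

  # different seeds give different file bytes
  tmp2 <- withr::local_tempdir()
  generate_dataset(4, dir = tmp2, seed = 6)
  generate_dataset(4, dir = file.path(tmp2, "b"), seed = 7)
  h1 <- tools::md5sum(file.path(tmp2, "syn_0001.png"))
  h2 <- tools::md5sum(file.path(tmp2, "b", "syn_0001.png"))
  expect_false(unname(h1) == unname(h2))
})

test_that("oracle backends plant exactly the promised heatmaps", {
  ds <- prepare_dataset(generate_dataset(6, seed = 8, balance = 0), size = 64)
  withcal <- which(vapply(ds$annotation,
                          function(a) nrow(a$calcifications) > 0, logical(1)))
  expect_gt(length(withcal), 0)
  i <- withcal[1]
  img <- ds$image[[i]]; ann <- ds$annotation[[i]]

  hot <- oracle_backend("calcification_hot", prediction = "truth")
  hm <- generate_heatmap(hot, img, annotation = ann)
  calc <- calcification_region(ann, c(64, 64))
  expect_equal(significant_ratio(hm, calc), 1)

  zero <- oracle_backend("zero", prediction = "truth")
  hm0 <- generate_heatmap(zero, img, annotation = ann)
  expect_equal(significant_ratio(hm0, calc), 0)
  interior <- lesion_interior_mask(ann, c(64, 64))
  expect_equal(significant_ratio(hm0, interior), 0)

  ih <- oracle_backend("interior_hot", prediction = "truth")
  hmi <- generate_heatmap(ih, img, annotation = ann)
  expect_equal(significant_ratio(hmi, interior), 1)
  # calcifications are planted inside the lesion, so they are hot too
  expect_equal(significant_ratio(hmi, calc), 1)

  expect_error(oracle_backend("nope"), "arg")
  expect_equal(predict_class(hot, img, ann)$class, ann$class)
  always <- oracle_backend("zero", prediction = "malignant")
  expect_equal(predict_class(always, img, ann)$class, "malignant")
})
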