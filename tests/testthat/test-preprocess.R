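test_that("eval-mode image preprocessing standardizes per channel", {
  set.seed(4)
  img <- random_image(20, 24, 2)
  out <- preprocess_image(img, target_size = c(20, 24))
  for (ch in 1:2) {
    expect_equal(mean(out[, , ch]), 0, tolerance = 1e-12)
    expect_equal(mean(out[, , ch]^2), 1, tolerance = 1e-8)
  }
})

test_that("a constant image standardizes to all zeros", {
  img <- array(3.7, dim = c(8, 8, 3))
  out <- preprocess_image(img, target_size = c(8, 8))
  expect_true(all(out == 0))
})

test_that("eval-mode preprocessing equals independent resize + z-score", {
  set.seed(11)
  img <- random_image(64, 64, 3)
  out <- preprocess_image(img, target_size = c(32, 32))
  for (ch in 1:3) {
    res <- EBImage::imageData(EBImage::resize(EBImage::Image(img[, , ch]),
                                              w = 32, h = 32,
                                              filter = "bilinear"))
    z <- (res - mean(res)) / sqrt(mean((res - mean(res))^2))
    expect_equal(out[, , ch], matrix(z, 32, 32), tolerance = 1e-12)
  }
})

test_that("train-mode augmentation is seeded and shape-preserving", {
  set.seed(5)
  img <- random_image(32, 32, 1)
  a1 <- preprocess_image(img, c(32, 32), train_mode = TRUE, seed = 42)
  a2 <- preprocess_image(img, c(32, 32), train_mode = TRUE, seed = 42)
  a3 <- preprocess_image(img, c(32, 32), train_mode = TRUE, seed = 43)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_equal(dim(a1), c(32L, 32L, 1L))
  expect_equal(mean(a1), 0, tolerance = 1e-12)
})

test_that("lab scaling maps training min/max to [0, 1] endpoints", {
  stats <- lab_stats(list(matrix(c(2, 4, 6), 3, 1)))
  out <- preprocess_lab(matrix(c(2, 4, 6), 3, 1), stats)
  expect_equal(drop(out), c(0, 0.5, 1))
})

test_that("missing lab values are imputed with the training median", {
  train <- list(matrix(c(1, 2, 3), 3, 1))
  stats <- lab_stats(train)
  expect_equal(stats$median, 2)
  out <- preprocess_lab(matrix(c(1, NA, 3), 3, 1), stats)
  ## after scaling with min 1 / max 3, the imputed 2 sits at 0.5
  expect_equal(drop(out), c(0, 0.5, 1))
})

test_that("temporal interpolation matches piecewise-linear evaluation", {
  train <- list(matrix(c(0, 1, 0, 1), 4, 1))
  stats <- lab_stats(train)
  out <- preprocess_lab(matrix(c(0, 1, 0, 1), 4, 1), stats, T_target = 7)
  expect_equal(drop(out), c(0, 0.5, 1, 0.5, 0, 0.5, 1))
})

test_that("a constant training feature scales to 0.5", {
  stats <- lab_stats(list(matrix(5, 4, 1)))
  out <- preprocess_lab(matrix(c(5, 5, 5, 5), 4, 1), stats)
  expect_true(all(out == 0.5))
})

test_that("values outside mean +/- 3 sd are replaced before scaling", {
  set.seed(8)
  train <- list(matrix(rnorm(400), 100, 4))
  stats <- lab_stats(train)
  ser <- matrix(rnorm(40), 10, 4)
  ser[3, 2] <- 1e4                      # gross outlier
  out <- preprocess_lab(ser, stats)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(out[3, 2], stats$median_scaled[2])
})

test_that("scaling with unit training stats is idempotent", {
  stats <- lab_stats(list(matrix(c(0, 1, 0.5, 0.2), 4, 1)))
  once <- preprocess_lab(matrix(c(0, 1, 0.5, 0.2), 4, 1), stats)
  twice <- preprocess_lab(once, stats)
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("image noise perturbation has the advertised variance", {
  img <- array(0, dim = c(100, 100, 1))
  expect_identical(perturb_image_noise(img, 0), img)
  out <- perturb_image_noise(img, 0.4, v_max = 1, seed = 6)
  expect_equal(var(as.vector(out - img)), 0.4, tolerance = 0.03)
  expect_identical(perturb_image_noise(img, 0.4, seed = 6),
                   perturb_image_noise(img, 0.4, seed = 6))
  expect_error(perturb_image_noise(img, 1.5), "range")
})

test_that("lab masking replaces exactly the requested number of entries", {
  set.seed(9)
  train <- random_labs(5, 10, 8)
  stats <- lab_stats(train)
  ser <- matrix(runif(80, 0.4, 0.6), 10, 8)   # avoid median collisions
  expect_identical(perturb_lab_missing(ser, 0, stats), ser)
  out <- perturb_lab_missing(ser, 0.25, stats, seed = 2)
  expect_equal(sum(out != ser), 20)
  full <- perturb_lab_missing(ser, 1, stats, seed = 2)
  expect_equal(full, matrix(stats$median_scaled, 10, 8, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("stratified split hits the requested per-class proportions", {
  labels <- rep(0:3, each = 25)
  sp <- stratified_split(labels, seed = 10)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$val), 20)
  expect_equal(length(sp$test), 10)
  for (c in 0:3) {
    expect_true(sum(labels[sp$train] == c) %in% 17:18)
    expect_equal(sum(labels[sp$val] == c), 5)
    expect_true(sum(labels[sp$test] == c) %in% 2:3)
  }
  expect_identical(sp, stratified_split(labels, seed = 10))
  expect_false(identical(sp, stratified_split(labels, seed = 11)))
  expect_error(stratified_split(labels, ratios = c(0.6, 0.3, 0.2)), "sum")
})

test_that("a single-class dataset still splits 70/20/10", {
  sp <- stratified_split(rep(0L, 100), seed = 1)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 70L, val = 20L, test = 10L))
})
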