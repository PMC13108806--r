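test_that("generation is deterministic and validates its spec", {
  spec <- synth_spec(n_samples = 20, n_classes = 2, image_size = c(16, 16, 1),
                     T_steps = 5, K = 4, seed = 3, patch = 8)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$samples, d2$samples)

  expect_error(synth_spec(0, 2), "n_samples")
  expect_error(synth_spec(10, 0), "n_classes")
  expect_error(synth_spec(10, 2, redundant_fraction = 1), "redundant_fraction")
  expect_error(synth_spec(10, 2, image_size = c(30, 32, 3), patch = 16),
               "divisible")
})

test_that("zero signal strength plants no class structure in the images", {
  ds <- generate_dataset(synth_spec(
    n_samples = 200, n_classes = 2, image_size = c(16, 16, 1), T_steps = 4,
    K = 4, signal_strength = 0, cross_modal_coupling = 0,
    redundant_fraction = 0, seed = 5, patch = 8, missing_rate = 0))
  labels <- vapply(ds$samples, `[[`, integer(1), "label")
  means <- lapply(0:1, function(c) {
    imgs <- lapply(ds$samples[labels == c], `[[`, "image")
    Reduce(`+`, imgs) / length(imgs)
  })
  ## class-conditional mean images agree up to sampling noise of N(0,1)/n
  se <- sqrt(1 / sum(labels == 0) + 1 / sum(labels == 1))
  expect_lt(max(abs(means[[1]] - means[[2]])), 5 * se)
})

test_that("redundant lab dimensions carry no class signal, the rest do", {
  spec <- synth_spec(n_samples = 600, n_classes = 4,
                     image_size = c(32, 32, 3), T_steps = 10, K = 8,
                     redundant_fraction = 0.5, seed = 7, missing_rate = 0)
  ds <- generate_dataset(spec)
  noise_dims <- attr(ds, "noise_dims")
  signal_dims <- attr(ds, "signal_dims")
  expect_length(noise_dims, 4L)
  labels <- vapply(ds$samples, `[[`, integer(1), "label")
  pvals <- vapply(seq_len(8), function(k) {
    v <- vapply(ds$samples, function(s) mean(s$lab[, k]), numeric(1))
    summary(aov(v ~ factor(labels)))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_true(all(pvals[signal_dims] < 1e-6))
  expect_true(all(pvals[noise_dims] > 0.001))
})

test_that("class counts are balanced up to rounding", {
  ds <- generate_dataset(synth_spec(n_samples = 50, n_classes = 4,
                                    image_size = c(16, 16, 1), patch = 8,
                                    seed = 2))
  tab <- table(vapply(ds$samples, `[[`, integer(1), "label"))
  expect_equal(length(tab), 4L)
  expect_lte(max(tab) - min(tab), 1)
})

test_that("the on-disk layout round-trips labels exactly and images closely", {
  ds <- tiny_dataset(n = 9, seed = 21)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labs.csv")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_dataset(dir)
  expect_equal(length(back$samples), 9L)
  for (i in seq_along(ds$samples)) {
    expect_identical(back$samples[[i]]$label, ds$samples[[i]]$label)
    expect_identical(back$samples[[i]]$sample_id, ds$samples[[i]]$sample_id)
    expect_equal(back$samples[[i]]$lab, ds$samples[[i]]$lab,
                 ignore_attr = TRUE)
    ## 8-bit quantization behind the recorded affine transform
    rng <- diff(range(vapply(ds$samples, function(s) range(s$image),
                             numeric(2))))
    expect_lt(max(abs(back$samples[[i]]$image - ds$samples[[i]]$image)),
              rng / 255)
  }
})

test_that("nearest-class-mean on raw lab features recovers strong signal", {
  ds <- generate_dataset(preset_strong_signal(seed = 13, n_samples = 200))
  labels <- vapply(ds$samples, `[[`, integer(1), "label")
  feats <- t(vapply(ds$samples, function(s) {
    v <- as.vector(s$lab); v[is.na(v)] <- 0; v
  }, numeric(80)))
  train <- seq_len(150); test <- 151:200
  mus <- sapply(0:3, function(c)
    colMeans(feats[intersect(train, which(labels == c)), , drop = FALSE]))
  pred <- apply(feats[test, ], 1, function(x)
    which.min(colSums((mus - x)^2)) - 1)
  expect_gt(mean(pred == labels[test]), 0.9)
})
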