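test_that("loss components combine exactly and hit the worked values", {
  ## perfect prediction, aligned embeddings, empty mask
  l <- loss_total(c(1, 0), 0L, c(1, 1), c(2, 2), rep(0, 4))
  expect_equal(l$cls, 0, tolerance = 1e-12)
  expect_equal(l$cm, 0, tolerance = 1e-12)
  expect_equal(l$sparse, 0)
  expect_equal(l$total, 0, tolerance = 1e-12)

  ## arithmetic composition 1.0 + 0.1*0.5 + 0.05*0.4 = 1.07
  p <- c(exp(-1), 1 - exp(-1))
  l2 <- loss_total(p, 0L, c(1, 0), c(1, 1), rep(0.4, 10),
                   alpha = 0.1, beta = 0.05)
  expect_equal(l2$cls, 1, tolerance = 1e-12)
  expect_equal(l2$cm, 1 - sqrt(0.5), tolerance = 1e-12)
  expect_equal(l2$sparse, 0.4)
  expect_identical(l2$total, l2$cls + 0.1 * l2$cm + 0.05 * l2$sparse)

  ## orthogonal embeddings give alignment loss exactly 1
  l3 <- loss_total(c(0.5, 0.5), 1L, c(1, 0), c(0, 1), 1)
  expect_equal(l3$cm, 1)

  ## zero probability on the true class is clamped, not infinite
  l4 <- loss_total(c(1, 0), 1L, c(1, 0), c(1, 0), 0)
  expect_true(is.finite(l4$cls))
  expect_equal(l4$cls, -log(1e-12))
})

test_that("count-based metrics match their closed forms", {
  expect_equal(accuracy_from_counts(10, 5, 0, 0), 1)
  expect_equal(accuracy_from_counts(45, 40, 5, 10), 0.85)
  expect_equal(accuracy_from_counts(0, 0, 3, 2), 0)
  expect_error(accuracy_from_counts(0, 0, 0, 0), "total")

  expect_equal(f1_from_counts(8, 2, 2), 0.8)
  expect_equal(f1_from_counts(0, 5, 5), 0)
  expect_equal(f1_from_counts(7, 0, 0), 1)

  expect_equal(kappa_from_confusion(diag(c(3, 5, 2))), 1)
  expect_equal(kappa_from_confusion(matrix(c(40, 10, 10, 40), 2)), 0.6)
  expect_equal(kappa_from_confusion(matrix(25, 2, 2)), 0)
})

test_that("AUC is the pairwise rank statistic with half-weight ties", {
  expect_equal(auc_from_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_from_scores(c(0.8, 0.2, 0.6, 0.4), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_from_scores(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_from_scores(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("sparsity and cosine similarity follow their definitions", {
  expect_equal(feature_sparsity(rep(0, 5)), 100)
  expect_equal(feature_sparsity(1:5), 0)
  expect_equal(feature_sparsity(c(1, 0, 2, 0, 3, 0, 0, 0)), 62.5)
  expect_error(feature_sparsity(numeric(0)), "nonempty")

  v <- rnorm(6)
  expect_equal(cross_modal_similarity(v, 2 * v), 1)
  expect_equal(cross_modal_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cross_modal_similarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(cross_modal_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("metrics agree with brute force on 500 random confusion matrices", {
  set.seed(40)
  for (i in 1:500) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 8), C, C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    expect_equal(sum(diag(cm)) / sum(cm), oracle_accuracy(cm),
                 tolerance = 1e-9)
    expect_equal(f1_macro_from_confusion(cm), oracle_f1_macro(cm),
                 tolerance = 1e-9)
    k <- kappa_from_confusion(cm)
    expect_equal(k, oracle_kappa(cm), tolerance = 1e-9)
    expect_gte(k, -1)
    expect_lte(k, 1)
  }
})

test_that("AUC matches pair enumeration, trapezoid integration and pROC", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 3), 1))   # induce occasional ties
    expect_equal(auc_from_scores(s, y), oracle_auc(s, y == 1),
                 tolerance = 1e-9)
  }
  for (i in 1:50) {
    n <- sample(8:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- rnorm(n)                              # ties-free
    expect_equal(auc_from_scores(s, y), oracle_auc_trapezoid(s, y == 1),
                 tolerance = 1e-9)
  }
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:25) {
    y <- c(0, 1, rbinom(28, 1, 0.4))
    s <- rnorm(30)
    expect_equal(auc_from_scores(s, y),
                 as.numeric(pROC::auc(pROC::roc(
                   y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))),
                 tolerance = 1e-9)
  }
})

test_that("kappa agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(43)
  for (i in 1:50) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 6) + 1, C, C)
    expect_equal(kappa_from_confusion(cm),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-9)
  }
})

test_that("parameter counting follows shape arithmetic and freezing", {
  w <- list(W = matrix(0, 12, 768), b = numeric(768))
  expect_equal(count_parameters(w), 12 * 768 + 768)
  lab_enc <- list(lab_W1 = matrix(0, 12, 384), lab_b1 = numeric(384),
                  lab_W2 = matrix(0, 384, 768), lab_b2 = numeric(768))
  expect_equal(count_parameters(lab_enc),
               (12 * 384 + 384) + (384 * 768 + 768))
  m <- cmf_model(tiny_config(), seed = 1)
  expect_equal(count_parameters(m),
               sum(vapply(m$params, length, numeric(1))))
  m$trainable[] <- FALSE
  expect_equal(count_parameters(m), 0)
})

test_that("FLOP estimates are linear in batch and sum per-layer counts", {
  m <- cmf_model(tiny_config(), seed = 1)
  tab <- estimate_flops(m, breakdown = TRUE)
  expect_equal(estimate_flops(m), sum(tab$flops))
  expect_equal(estimate_flops(m, batch = 2), 2 * estimate_flops(m))
  ## hand count of one named layer: scorer is a 2d -> 2d linear map
  d <- m$config$d
  expect_equal(tab$flops[tab$layer == "smarttrim_scorer"],
               2 * (2 * d)^2 + 2 * d)
  ## vector-mode fusion counts only the value projection
  expect_equal(tab$flops[tab$layer == "fusion_value_proj"], 2 * d * d)
})
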