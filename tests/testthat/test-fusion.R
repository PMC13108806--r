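test_that("vector-mode attention collapses to the value projection", {
  set.seed(30)
  d <- 6L
  w <- list(W_q = matrix(rnorm(d * d), d, d),
            W_k = matrix(rnorm(d * d), d, d),
            W_v = matrix(rnorm(d * d), d, d))
  fi <- rnorm(d); fl <- rnorm(d)
  expect_equal(cross_modal_attention(fi, fl, w, tokens = 1),
               drop(fl %*% w$W_v), tolerance = 1e-12)
})

test_that("token-mode attention with identical key/value tokens is uniform", {
  set.seed(31)
  d <- 8L; m <- 4L
  w <- list(W_q = matrix(rnorm(d * d), d, d),
            W_k = diag(d), W_v = diag(d))
  fl <- rep(rnorm(d / m), m)              # identical tokens after reshape
  out <- cross_modal_attention(rnorm(d), fl, w, tokens = m)
  expect_equal(out, fl, tolerance = 1e-12)
})

test_that("token-mode attention matches hand-computed softmax(QK'/sqrt)V", {
  set.seed(32)
  d <- 4L; m <- 2L; dm <- 2L
  w <- list(W_q = matrix(rnorm(16), 4, 4), W_k = matrix(rnorm(16), 4, 4),
            W_v = matrix(rnorm(16), 4, 4))
  fi <- rnorm(4); fl <- rnorm(4)
  q <- drop(fi %*% w$W_q); k <- drop(fl %*% w$W_k); v <- drop(fl %*% w$W_v)
  Qt <- rbind(q[1:2], q[3:4]); Kt <- rbind(k[1:2], k[3:4])
  Vt <- rbind(v[1:2], v[3:4])
  sc <- Qt %*% t(Kt) / sqrt(2)
  P <- t(apply(sc, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(cross_modal_attention(fi, fl, w, tokens = 2),
               as.vector(t(P %*% Vt)), tolerance = 1e-12)
  expect_error(cross_modal_attention(rnorm(6), rnorm(6),
                                     list(W_q = diag(6), W_k = diag(6),
                                          W_v = diag(6)), tokens = 4),
               "divisible")
})

test_that("residual + layer norm meets the normalization contract", {
  ## cancelling inputs: the epsilon-stabilized norm of zero is zero
  fi <- rnorm(8)
  expect_equal(fuse_residual_norm(-fi, fi), rep(0, 8))
  set.seed(33)
  out <- fuse_residual_norm(rnorm(16), rnorm(16))
  expect_equal(mean(out), 0, tolerance = 1e-10)
  expect_equal(mean(out^2), 1, tolerance = 1e-4)
  x <- c(1, 2, 3, 4)
  expect_equal(fuse_residual_norm(x, rep(0, 4)),
               (x - 2.5) / sqrt(mean((x - 2.5)^2) + 1e-5), tolerance = 1e-12)
  expect_error(fuse_residual_norm(rnorm(4), rnorm(5)), "mismatch")
})

test_that("the prediction head lands on the simplex with known limits", {
  d <- 8L; C <- 3L
  zero_w <- list(W_b = matrix(0, d, 4), b_b = numeric(4),
                 W_o = matrix(0, 4, C), b_o = numeric(C))
  out <- predict_head(rnorm(d), zero_w)
  expect_equal(out$probs, rep(1 / C, C))

  sat <- zero_w
  sat$b_o <- c(50, 0, 0)
  expect_equal(predict_head(rnorm(d), sat)$probs, c(1, 0, 0),
               tolerance = 1e-20)

  set.seed(34)
  w <- list(W_b = matrix(rnorm(d * 4, sd = 0.5), d, 4), b_b = rnorm(4),
            W_o = matrix(rnorm(4 * C, sd = 0.5), 4, C), b_o = rnorm(C))
  f <- rnorm(d)
  ref_r <- pmax(drop(f %*% w$W_b) + w$b_b, 0)
  ref_l <- drop(ref_r %*% w$W_o) + w$b_o
  ref_p <- exp(ref_l - max(ref_l)); ref_p <- ref_p / sum(ref_p)
  out <- predict_head(f, w)
  expect_equal(out$f_refine, ref_r, tolerance = 1e-12)
  expect_equal(out$probs, ref_p, tolerance = 1e-12)
  expect_equal(sum(out$probs), 1, tolerance = 1e-12)
  expect_error(predict_head(f, list(W_b = w$W_b, b_b = w$b_b,
                                    W_o = matrix(0, 4, 1), b_o = 0)),
               "classes")
})

test_that("forward_full respects ablation toggles and is reproducible", {
  set.seed(35)
  sample <- list(image = random_image(), lab = matrix(runif(20), 4, 5))
  sample$image <- preprocess_image(sample$image, c(16, 16))

  cfg_off <- tiny_config(smarttrim = FALSE)
  m_off <- cmf_model(cfg_off, seed = 8)
  st <- forward_full(sample, m_off)
  expect_identical(st$pruning$f_prune, st$features$f_cat)
  expect_true(all(st$pruning$mask == 1))

  cfg_nocmt <- tiny_config(fusion = FALSE)
  m_nocmt <- cmf_model(cfg_nocmt, seed = 8)
  st2 <- forward_full(sample, m_nocmt)
  expect_null(st2$fusion$attn)
  expect_equal(st2$fusion$f_fusion,
               drop(st2$pruning$f_prune %*% m_nocmt$params$ad_W) +
                 m_nocmt$params$ad_b,
               tolerance = 1e-12)

  m_full <- cmf_model(tiny_config(), seed = 8)
  a <- forward_full(sample, m_full)
  b <- forward_full(sample, m_full)
  expect_identical(a, b)
  expect_equal(sum(a$fusion$probs), 1, tolerance = 1e-9)
  ## concatenation halves are the encoder outputs exactly
  expect_identical(a$features$f_cat[1:16], a$features$f_i)
  expect_identical(a$features$f_cat[17:32], a$features$f_l)
  expect_true(all(a$features$f_l >= 0))
})

test_that("the fused feature is sensitive to the image branch", {
  set.seed(36)
  d <- 8L
  w <- list(W_q = diag(d), W_k = diag(d), W_v = matrix(rnorm(d * d), d, d))
  fi <- rnorm(d); fl <- rnorm(d)
  base <- fuse_residual_norm(cross_modal_attention(fi, fl, w), fi)
  bump <- fi; bump[3] <- bump[3] + 0.5
  pert <- fuse_residual_norm(cross_modal_attention(bump, fl, w), bump)
  expect_false(isTRUE(all.equal(base, pert)))
})
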