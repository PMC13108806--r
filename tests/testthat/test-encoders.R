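test_that("patchify produces the forced patch count and round-trips", {
  img <- array(rnorm(224 * 224 * 3), c(224, 224, 3))
  expect_equal(dim(patchify(img, 16))[1], 196L)
  small <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  pt <- patchify(small, 16)
  expect_equal(dim(pt), c(4L, 16L, 16L, 3L))
  expect_identical(unpatchify(pt, 32, 32), small)
  bad <- array(0, c(33, 32, 3))
  expect_error(patchify(bad, 16), "height")
})

test_that("patch embedding is linear in its parts", {
  set.seed(2)
  P <- 4L; CH <- 2L; d <- 6L
  img <- array(rnorm(8 * 8 * CH), c(8, 8, CH))
  pt <- patchify(img, P)
  N <- dim(pt)[1]
  zero_w <- list(patch_W = matrix(0, P * P * CH, d), patch_b = numeric(d),
                 cls = numeric(d), pos = matrix(0, N + 1, d))
  expect_true(all(embed_patches(pt, zero_w) == 0))

  pos_w <- zero_w
  pos_w$pos <- matrix(rnorm((N + 1) * d), N + 1, d)
  expect_equal(embed_patches(pt, pos_w), pos_w$pos)

  w <- list(patch_W = matrix(rnorm(P * P * CH * d), P * P * CH, d),
            patch_b = rnorm(d), cls = rnorm(d),
            pos = matrix(rnorm((N + 1) * d), N + 1, d))
  emb <- embed_patches(pt, w)
  ## row n+1 equals flatten(patch_n) %*% W + b + pos row, by direct arithmetic
  for (n in c(1L, N)) {
    flat <- as.vector(pt[n, , , ])
    expect_equal(emb[n + 1L, ],
                 drop(flat %*% w$patch_W) + w$patch_b + w$pos[n + 1L, ],
                 tolerance = 1e-12)
  }
  expect_equal(emb[1L, ], w$cls + w$pos[1L, ], tolerance = 1e-12)
})

test_that("depth-0 encoder returns the embedded class token unchanged", {
  cfg <- cmf_config(d = 8L, heads = 1L, depth = 0L, n_classes = 2L,
                    image_size = c(8L, 8L, 1L), patch = 4L, T_steps = 3L,
                    K = 3L)
  m <- cmf_model(cfg, seed = 4)
  img <- array(rnorm(64), c(8, 8, 1))
  f <- encode_image(img, m)
  emb <- embed_patches(patchify(img, 4L),
                       list(patch_W = m$params$patch_W,
                            patch_b = m$params$patch_b,
                            cls = m$params$cls, pos = m$params$pos))
  expect_equal(f, emb[1, ], tolerance = 1e-12)
})

test_that("position embeddings break patch permutation symmetry", {
  cfg <- cmf_config(d = 8L, heads = 1L, depth = 1L, n_classes = 2L,
                    image_size = c(8L, 8L, 1L), patch = 4L, T_steps = 3L,
                    K = 3L, residual_scale = 1)
  m <- cmf_model(cfg, seed = 6)
  set.seed(7)
  img <- array(rnorm(64), c(8, 8, 1))
  swapped <- img
  swapped[1:4, 1:4, ] <- img[1:4, 5:8, ]
  swapped[1:4, 5:8, ] <- img[1:4, 1:4, ]
  expect_false(isTRUE(all.equal(encode_image(img, m),
                                encode_image(swapped, m))))
  ## with zero position embeddings the class token sees an unordered set
  m0 <- m
  m0$params$pos[] <- 0
  expect_equal(encode_image(img, m0), encode_image(swapped, m0),
               tolerance = 1e-10)
})

test_that("one-block one-head encoder matches a hand-unrolled computation", {
  cfg <- cmf_config(d = 8L, heads = 1L, depth = 1L, n_classes = 2L,
                    image_size = c(8L, 8L, 1L), patch = 4L, T_steps = 3L,
                    K = 3L, residual_scale = 1)
  m <- cmf_model(cfg, seed = 11)
  set.seed(12)
  img <- array(rnorm(64), c(8, 8, 1))
  p <- m$params
  emb <- embed_patches(patchify(img, 4L),
                       list(patch_W = p$patch_W, patch_b = p$patch_b,
                            cls = p$cls, pos = p$pos))
  w <- list(ln1_g = p$blk1_ln1_g, ln1_b = p$blk1_ln1_b,
            Wq = p$blk1_Wq, bq = p$blk1_bq, Wk = p$blk1_Wk, bk = p$blk1_bk,
            Wv = p$blk1_Wv, bv = p$blk1_bv, Wo = p$blk1_Wo, bo = p$blk1_bo,
            ln2_g = p$blk1_ln2_g, ln2_b = p$blk1_ln2_b,
            W1 = p$blk1_W1, b1 = p$blk1_b1, W2 = p$blk1_W2, b2 = p$blk1_b2)
  expect_equal(encode_image(img, m), oracle_tiny_transformer(emb, w),
               tolerance = 1e-10)
})

test_that("lab encoder matches its closed form and is nonnegative", {
  set.seed(14)
  K <- 5L; dh <- 4L; d <- 6L
  w <- list(lab_W1 = matrix(rnorm(K * dh), K, dh), lab_b1 = rnorm(dh),
            lab_W2 = matrix(rnorm(dh * d), dh, d), lab_b2 = rnorm(d))
  zw <- list(lab_W1 = w$lab_W1, lab_b1 = numeric(dh),
             lab_W2 = w$lab_W2, lab_b2 = numeric(d))
  expect_true(all(encode_lab(matrix(0, 3, K), zw) == 0))

  r1 <- runif(K)
  mlp <- function(x) pmax(drop(pmax(drop(x %*% w$lab_W1) + w$lab_b1, 0) %*%
                                 w$lab_W2) + w$lab_b2, 0)
  expect_equal(encode_lab(matrix(r1, 1, K), w), mlp(r1), tolerance = 1e-12)

  r2 <- runif(K)
  expect_equal(encode_lab(rbind(r1, r2), w), (mlp(r1) + mlp(r2)) / 2,
               tolerance = 1e-12)

  for (i in 1:20) {
    ser <- matrix(runif(4 * K), 4, K)
    expect_true(all(encode_lab(ser, w) >= 0))
  }
  expect_error(encode_lab(matrix(0, 3, K + 1), w), "features")
})

test_that("both encoders land in the same embedding dimension", {
  cfg <- tiny_config()
  m <- cmf_model(cfg, seed = 3)
  set.seed(15)
  f_i <- encode_image(random_image(), m)
  f_l <- encode_lab(matrix(runif(4 * 5), 4, 5), m)
  expect_length(f_i, cfg$d)
  expect_length(f_l, cfg$d)
})
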