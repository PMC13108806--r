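## Model container: configuration, Xavier initialization, batched forward
## pass, and hand-derived reverse-mode gradients for every trainable array.
## All dense maps use the row-vector convention y = x %*% W (W is in x out),
## which keeps the printed weight shapes (e.g. W1 in R^{K x d/2}) literal.

#' Model configuration
#'
#' Defaults are the desk-scale ("toy") configuration exercised by the test
#' suite; the full-scale backbone (`d = 768`, `depth = 12`, 224 x 224 input)
#' is constructible with the same fields.
#'
#' @param d Embedding dimension shared by both modality encoders.
#' @param patch Patch size in pixels (images must be divisible by it).
#' @param depth Number of transformer encoder blocks.
#' @param heads Attention heads per block (`d` must be divisible).
#' @param mlp_ratio Feed-forward expansion ratio inside each block.
#' @param lab_hidden Hidden width of the laboratory MLP (default `d/2`).
#' @param image_size `c(H, W, channels)` of the preprocessed input images.
#' @param T_steps,K Laboratory series shape (time steps, features).
#' @param n_classes Number of classes `C` (>= 2).
#' @param lambda SmartTrim threshold coefficient (default 0.3).
#' @param temperature Straight-through relaxation temperature (default 0.1).
#' @param smarttrim Enable the SmartTrim gate (ablation toggle).
#' @param fusion Enable cross-modal attention fusion; when disabled the head
#'   consumes the gated concatenation through a linear 2d -> d adapter.
#' @param tokens Tokens per branch in the fusion attention. 1 (default)
#'   implements the single-vector equations literally, in which case the
#'   softmax over the single key is identically 1 and the attention output
#'   equals `W_V` applied to the laboratory branch.
#' @param image_encoder `"vit"` (patch-token transformer) or `"conv"` (the
#'   3-block convolutional substitute used by the ablation protocol).
#' @param conv_channels Channel widths of the convolutional substitute.
#' @param residual_scale Factor applied at initialization to each transformer
#'   block's output projections (attention out-projection and second MLP
#'   weight), so blocks start close to identity. Training medical-scale
#'   transformers from scratch on small cohorts is unstable with full-scale
#'   residual branches; down-scaling them keeps the randomly initialized
#'   image stream from drowning the laboratory stream early in training
#'   (default 0.01; set to 1 for the plain initialization).
#' @param scorer_init_scale Factor applied at initialization to the SmartTrim
#'   scorer weights. The default 0 starts every importance score at exactly
#'   0.5, so the gate is fully open at the start of training (the inclusive
#'   threshold rule keeps a constant score vector intact) and any score
#'   differentiation is learned rather than inherited from random
#'   initialization — the usual zero-init convention for gating layers.
#' @param lab_init_gain Factor applied at initialization to the laboratory
#'   MLP weights. Laboratory inputs live in `[0, 1]` after min--max scaling,
#'   which under plain Xavier initialization leaves `F_L` an order of
#'   magnitude smaller than the image embedding; a modest gain rebalances
#'   the two streams at the start of training (default 2).
#' @param ln_eps Layer-norm stabilizer.
#' @return List of class `cmf_config`.
#' @export
cmf_config <- function(d = 64L, patch = 16L, depth = 2L, heads = 4L,
                       mlp_ratio = 4, lab_hidden = NULL,
                       image_size = c(32L, 32L, 3L), T_steps = 10L, K = 8L,
                       n_classes = 4L, lambda = 0.3, temperature = 0.1,
                       smarttrim = TRUE, fusion = TRUE, tokens = 1L,
                       image_encoder = c("vit", "conv"),
                       conv_channels = c(8L, 16L, 32L), residual_scale = 0.01,
                       scorer_init_scale = 0, lab_init_gain = 2,
                       ln_eps = 1e-5) {
  image_encoder <- match.arg(image_encoder)
  check_number(d, "d", lower = 4, integer = TRUE)
  check_number(n_classes, "n_classes", lower = 2, integer = TRUE)
  if (d %% heads != 0) stop_cmf("'d' must be divisible by 'heads'")
  if (d %% tokens != 0) stop_cmf("'d' must be divisible by 'tokens'")
  if (image_encoder == "vit" &&
      (image_size[1] %% patch != 0 || image_size[2] %% patch != 0))
    stop_cmf(sprintf("image size %dx%d not divisible by patch %d",
                     image_size[1], image_size[2], patch))
  if (image_encoder == "conv" &&
      (image_size[1] %% 8 != 0 || image_size[2] %% 8 != 0))
    stop_cmf("conv encoder needs H and W divisible by 8 (three 2x2 pools)")
  if (is.null(lab_hidden)) lab_hidden <- max(4L, d %/% 2L)
  check_number(lambda, "lambda", lower = 0)
  structure(list(
    d = as.integer(d), patch = as.integer(patch), depth = as.integer(depth),
    heads = as.integer(heads), mlp_ratio = mlp_ratio,
    lab_hidden = as.integer(lab_hidden), image_size = as.integer(image_size),
    T_steps = as.integer(T_steps), K = as.integer(K),
    n_classes = as.integer(n_classes), lambda = lambda,
    temperature = temperature, smarttrim = isTRUE(smarttrim),
    fusion = isTRUE(fusion), tokens = as.integer(tokens),
    image_encoder = image_encoder, conv_channels = as.integer(conv_channels),
    residual_scale = residual_scale, scorer_init_scale = scorer_init_scale,
    lab_init_gain = lab_init_gain, ln_eps = ln_eps,
    head_hidden = max(4L, d %/% 2L),
    n_patches = as.integer((image_size[1] %/% patch) *
                             (image_size[2] %/% patch))
  ), class = "cmf_config")
}

xavier <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

#' Build a model with Xavier-uniform initialized weights
#'
#' Weight matrices are Xavier-uniform, biases zero, layer-norm affine
#' identity, class token and position embeddings `N(0, 0.02^2)`. The
#' initialization draw order is fixed, so a given `(config, seed)` pair
#' always yields identical weights.
#'
#' @param config A [cmf_config()].
#' @param seed Integer seed for the initialization draws.
#' @return List of class `cmf_model` with `params` (named arrays),
#'   `trainable` (named logical), `config`, and (conv encoder only) the
#'   precomputed im2col index plan.
#' @export
cmf_model <- function(config, seed = 1L) {
  cf <- config
  d <- cf$d; dh <- cf$lab_hidden; dff <- as.integer(round(cf$d * cf$mlp_ratio))
  dh2 <- cf$head_hidden; CH <- cf$image_size[3]
  p <- list()
  conv_plan <- NULL
  with_seed(seed, {
    if (cf$image_encoder == "vit") {
      ppc <- cf$patch * cf$patch * CH
      p$patch_W <- xavier(ppc, d); p$patch_b <- numeric(d)
      p$cls <- stats::rnorm(d, 0, 0.02)
      p$pos <- matrix(stats::rnorm((cf$n_patches + 1L) * d, 0, 0.02),
                      cf$n_patches + 1L, d)
      for (i in seq_len(cf$depth)) {
        pre <- sprintf("blk%d_", i)
        p[[paste0(pre, "ln1_g")]] <- rep(1, d)
        p[[paste0(pre, "ln1_b")]] <- numeric(d)
        p[[paste0(pre, "Wq")]] <- xavier(d, d); p[[paste0(pre, "bq")]] <- numeric(d)
        p[[paste0(pre, "Wk")]] <- xavier(d, d); p[[paste0(pre, "bk")]] <- numeric(d)
        p[[paste0(pre, "Wv")]] <- xavier(d, d); p[[paste0(pre, "bv")]] <- numeric(d)
        p[[paste0(pre, "Wo")]] <- xavier(d, d) * cf$residual_scale
        p[[paste0(pre, "bo")]] <- numeric(d)
        p[[paste0(pre, "ln2_g")]] <- rep(1, d)
        p[[paste0(pre, "ln2_b")]] <- numeric(d)
        p[[paste0(pre, "W1")]] <- xavier(d, dff); p[[paste0(pre, "b1")]] <- numeric(dff)
        p[[paste0(pre, "W2")]] <- xavier(dff, d) * cf$residual_scale
        p[[paste0(pre, "b2")]] <- numeric(d)
      }
    } else {
      chans <- c(CH, cf$conv_channels)
      H <- cf$image_size[1]; W <- cf$image_size[2]
      conv_plan <- list()
      for (l in 1:3) {
        p[[sprintf("conv%d_W", l)]] <- xavier(9L * chans[l], chans[l + 1])
        p[[sprintf("conv%d_b", l)]] <- numeric(chans[l + 1])
        conv_plan[[l]] <- conv_im2col_plan(H, W, chans[l])
        H <- H %/% 2L; W <- W %/% 2L
      }
      p$convp_W <- xavier(chans[4], d); p$convp_b <- numeric(d)
    }
    p$lab_W1 <- xavier(cf$K, dh) * cf$lab_init_gain; p$lab_b1 <- numeric(dh)
    p$lab_W2 <- xavier(dh, d) * cf$lab_init_gain; p$lab_b2 <- numeric(d)
    if (cf$smarttrim) {
      p$st_W <- xavier(2L * d, 2L * d) * cf$scorer_init_scale
      p$st_b <- numeric(2L * d)
    }
    if (cf$fusion) {
      p$f_Wq <- xavier(d, d); p$f_Wk <- xavier(d, d); p$f_Wv <- xavier(d, d)
      p$f_ln_g <- rep(1, d); p$f_ln_b <- numeric(d)
    } else {
      p$ad_W <- xavier(2L * d, d); p$ad_b <- numeric(d)
    }
    p$h_Wb <- xavier(d, dh2); p$h_bb <- numeric(dh2)
    p$h_Wo <- xavier(dh2, cf$n_classes); p$h_bo <- numeric(cf$n_classes)
  })
  trainable <- rep(TRUE, length(p))
  names(trainable) <- names(p)
  structure(list(params = p, trainable = trainable, config = cf,
                 conv_plan = conv_plan), class = "cmf_model")
}

## ---- layer primitives (forward + backward) --------------------------------

layernorm_fwd <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(gy, cache, g) {
  xhat <- cache$xhat
  gxh <- sweep(gy, 2, g, "*")
  m1 <- rowMeans(gxh)
  m2 <- rowMeans(gxh * xhat)
  list(gx = (gxh - m1 - xhat * m2) * cache$inv,
       g_g = colSums(gy * xhat),
       g_b = colSums(gy))
}

linear_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

## Multi-head self-attention over B stacked sequences of S tokens.
mhsa_fwd <- function(Xn, B, S, heads, Wq, bq, Wk, bk, Wv, bv, Wo, bo) {
  d <- ncol(Xn); dk <- d %/% heads
  Q <- linear_fwd(Xn, Wq, bq)
  K <- linear_fwd(Xn, Wk, bk)
  V <- linear_fwd(Xn, Wv, bv)
  O <- matrix(0, nrow(Xn), d)
  P <- vector("list", B * heads)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(heads)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      sc <- (Q[rb, ch, drop = FALSE] %*% t(K[rb, ch, drop = FALSE])) / sqrt(dk)
      Pm <- softmax_rows(sc)
      O[rb, ch] <- Pm %*% V[rb, ch, drop = FALSE]
      P[[(b - 1L) * heads + h]] <- Pm
    }
  }
  A <- linear_fwd(O, Wo, bo)
  list(A = A, O = O, P = P, Q = Q, K = K, V = V)
}

mhsa_bwd <- function(gA, cache, B, S, heads, Xn, Wq, Wk, Wv, Wo) {
  d <- ncol(Xn); dk <- d %/% heads
  gO <- gA %*% t(Wo)
  g_Wo <- t(cache$O) %*% gA
  g_bo <- colSums(gA)
  gQ <- matrix(0, nrow(Xn), d); gK <- gQ; gV <- gQ
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(heads)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      Pm <- cache$P[[(b - 1L) * heads + h]]
      gOb <- gO[rb, ch, drop = FALSE]
      Vb <- cache$V[rb, ch, drop = FALSE]
      gP <- gOb %*% t(Vb)
      gV[rb, ch] <- t(Pm) %*% gOb
      gS <- Pm * (gP - rowSums(gP * Pm))
      gQ[rb, ch] <- gS %*% cache$K[rb, ch, drop = FALSE] / sqrt(dk)
      gK[rb, ch] <- t(gS) %*% cache$Q[rb, ch, drop = FALSE] / sqrt(dk)
    }
  }
  list(gX = gQ %*% t(Wq) + gK %*% t(Wk) + gV %*% t(Wv),
       g_Wq = t(Xn) %*% gQ, g_bq = colSums(gQ),
       g_Wk = t(Xn) %*% gK, g_bk = colSums(gK),
       g_Wv = t(Xn) %*% gV, g_bv = colSums(gV),
       g_Wo = g_Wo, g_bo = g_bo)
}

## ---- image encoder: patch-token transformer -------------------------------

## Stack patch-flattened images: returns (B*N) x (P*P*CH) matrix, sample-major.
images_to_patchflat <- function(images, P) {
  do.call(rbind, lapply(images, function(img) {
    pt <- patchify(img, P)
    matrix(aperm(pt, c(2, 3, 4, 1)), dim(pt)[1], byrow = TRUE)
  }))
}

vit_fwd <- function(model, Xp_flat, B) {
  cf <- model$config; p <- model$params
  d <- cf$d; N <- cf$n_patches; S <- N + 1L
  Xp <- linear_fwd(Xp_flat, p$patch_W, p$patch_b)
  X <- matrix(0, B * S, d)
  cls_rows <- seq(1L, B * S, by = S)
  X[cls_rows, ] <- matrix(p$cls, B, d, byrow = TRUE)
  X[-cls_rows, ] <- Xp
  X <- X + tile_rows(p$pos, B)
  blocks <- vector("list", cf$depth)
  for (i in seq_len(cf$depth)) {
    pre <- sprintf("blk%d_", i)
    ln1 <- layernorm_fwd(X, p[[paste0(pre, "ln1_g")]],
                         p[[paste0(pre, "ln1_b")]], cf$ln_eps)
    at <- mhsa_fwd(ln1$y, B, S, cf$heads,
                   p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]],
                   p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]],
                   p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]],
                   p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    Xmid <- X + at$A
    ln2 <- layernorm_fwd(Xmid, p[[paste0(pre, "ln2_g")]],
                         p[[paste0(pre, "ln2_b")]], cf$ln_eps)
    H1 <- linear_fwd(ln2$y, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    Hg <- gelu(H1)
    Ff <- linear_fwd(Hg, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    blocks[[i]] <- list(X_in = X, ln1 = ln1, at = at, Xmid = Xmid, ln2 = ln2,
                        H1 = H1, Hg = Hg)
    X <- Xmid + Ff
  }
  list(F_I = X[cls_rows, , drop = FALSE], blocks = blocks, Xp_flat = Xp_flat,
       cls_rows = cls_rows, B = B, S = S)
}

vit_bwd <- function(model, cache, g_FI) {
  cf <- model$config; p <- model$params
  B <- cache$B; S <- cache$S
  g <- list()
  gX <- matrix(0, B * S, cf$d)
  gX[cache$cls_rows, ] <- g_FI
  for (i in rev(seq_len(cf$depth))) {
    pre <- sprintf("blk%d_", i)
    bk <- cache$blocks[[i]]
    gF <- gX                       # residual: X_out = Xmid + Ff
    gXmid <- gX
    g[[paste0(pre, "W2")]] <- t(bk$Hg) %*% gF
    g[[paste0(pre, "b2")]] <- colSums(gF)
    gHg <- gF %*% t(p[[paste0(pre, "W2")]])
    gH1 <- gHg * gelu_grad(bk$H1)
    g[[paste0(pre, "W1")]] <- t(bk$ln2$y) %*% gH1
    g[[paste0(pre, "b1")]] <- colSums(gH1)
    gLn2y <- gH1 %*% t(p[[paste0(pre, "W1")]])
    l2 <- layernorm_bwd(gLn2y, bk$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- l2$g_g
    g[[paste0(pre, "ln2_b")]] <- l2$g_b
    gXmid <- gXmid + l2$gx
    gA <- gXmid                    # residual: Xmid = X_in + A
    gXin <- gXmid
    mb <- mhsa_bwd(gA, bk$at, B, S, cf$heads, bk$ln1$y,
                   p[[paste0(pre, "Wq")]], p[[paste0(pre, "Wk")]],
                   p[[paste0(pre, "Wv")]], p[[paste0(pre, "Wo")]])
    for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
      g[[paste0(pre, nm)]] <- mb[[paste0("g_", nm)]]
    l1 <- layernorm_bwd(mb$gX, bk$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- l1$g_g
    g[[paste0(pre, "ln1_b")]] <- l1$g_b
    gX <- gXin + l1$gx
  }
  g$pos <- rowsum(gX, rep(seq_len(S), times = B))
  dimnames(g$pos) <- NULL
  g$cls <- colSums(gX[cache$cls_rows, , drop = FALSE])
  gXp <- gX[-cache$cls_rows, , drop = FALSE]
  g$patch_W <- t(cache$Xp_flat) %*% gXp
  g$patch_b <- colSums(gXp)
  g
}

## ---- image encoder: convolutional substitute ------------------------------

## im2col index plan for a 3x3 same-padding convolution on H x W x Cin input,
## output pixels ordered column-major (row index fastest).
conv_im2col_plan <- function(H, W, Cin) {
  Hp <- H + 2L; Wp <- W + 2L
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * Cin)
  col <- 0L
  for (c in seq_len(Cin)) {
    off_c <- (c - 1L) * Hp * Wp
    for (dj in 0:2) {
      for (di in 0:2) {
        col <- col + 1L
        idx[, col] <- off_c + (oj + dj - 1L) * Hp + (oi + di)
      }
    }
  }
  list(H = H, W = W, Cin = Cin, idx = idx, npad = Hp * Wp * Cin)
}

conv_layer_fwd <- function(plan, W, b, x) {
  H <- plan$H; Wd <- plan$W; Cin <- plan$Cin
  ap <- array(0, c(H + 2L, Wd + 2L, Cin))
  ap[2:(H + 1L), 2:(Wd + 1L), ] <- x
  Xcol <- ap[plan$idx]
  dim(Xcol) <- dim(plan$idx)
  pre <- linear_fwd(Xcol, W, b)
  act <- relu(pre)
  arr <- array(act, c(H, Wd, ncol(W)))
  r <- seq(1L, H, 2L); cidx <- seq(1L, Wd, 2L)
  pooled <- (arr[r, cidx, , drop = FALSE] + arr[r + 1L, cidx, , drop = FALSE] +
             arr[r, cidx + 1L, , drop = FALSE] +
             arr[r + 1L, cidx + 1L, , drop = FALSE]) / 4
  list(out = pooled, Xcol = Xcol, pre = pre)
}

conv_layer_bwd <- function(plan, W, cache, g_pooled) {
  H <- plan$H; Wd <- plan$W; Cout <- ncol(W)
  garr <- array(0, c(H, Wd, Cout))
  r <- seq(1L, H, 2L); cidx <- seq(1L, Wd, 2L)
  q <- g_pooled / 4
  garr[r, cidx, ] <- q; garr[r + 1L, cidx, ] <- q
  garr[r, cidx + 1L, ] <- q; garr[r + 1L, cidx + 1L, ] <- q
  g_act <- matrix(garr, H * Wd, Cout)
  g_pre <- g_act * (cache$pre > 0)
  g_W <- t(cache$Xcol) %*% g_pre
  g_b <- colSums(g_pre)
  g_col <- g_pre %*% t(W)
  gp <- numeric(plan$npad)
  agg <- rowsum(as.vector(g_col), as.vector(plan$idx))
  gp[as.integer(rownames(agg))] <- agg
  gpa <- array(gp, c(H + 2L, Wd + 2L, plan$Cin))
  list(g_W = g_W, g_b = g_b,
       g_x = gpa[2:(H + 1L), 2:(Wd + 1L), , drop = FALSE])
}

conv_fwd <- function(model, images) {
  p <- model$params
  B <- length(images)
  d <- model$config$d
  F_I <- matrix(0, B, d)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    x <- images[[b]]
    lc <- vector("list", 3L)
    for (l in 1:3) {
      lc[[l]] <- conv_layer_fwd(model$conv_plan[[l]],
                                p[[sprintf("conv%d_W", l)]],
                                p[[sprintf("conv%d_b", l)]], x)
      x <- lc[[l]]$out
    }
    feat <- apply(x, 3, mean)
    F_I[b, ] <- drop(feat %*% p$convp_W) + p$convp_b
    caches[[b]] <- list(layers = lc, feat = feat, fdim = dim(x))
  }
  list(F_I = F_I, caches = caches)
}

conv_bwd <- function(model, cache, g_FI) {
  p <- model$params
  g <- list(convp_W = 0, convp_b = colSums(g_FI))
  for (l in 1:3) {
    g[[sprintf("conv%d_W", l)]] <- 0
    g[[sprintf("conv%d_b", l)]] <- 0
  }
  for (b in seq_along(cache$caches)) {
    cb <- cache$caches[[b]]
    gf <- g_FI[b, ]
    g$convp_W <- g$convp_W + outer(cb$feat, gf)
    g_feat <- drop(p$convp_W %*% gf)
    npix <- prod(cb$fdim[1:2])
    g_pool <- array(rep(g_feat / npix, each = npix), dim = cb$fdim)
    for (l in 3:1) {
      lb <- conv_layer_bwd(model$conv_plan[[l]], p[[sprintf("conv%d_W", l)]],
                           cb$layers[[l]], g_pool)
      g[[sprintf("conv%d_W", l)]] <- g[[sprintf("conv%d_W", l)]] + lb$g_W
      g[[sprintf("conv%d_b", l)]] <- g[[sprintf("conv%d_b", l)]] + lb$g_b
      g_pool <- lb$g_x
    }
  }
  g
}

## ---- full model forward ---------------------------------------------------

## Stack a list of T x K matrices into a (B*T) x K matrix, sample-major.
stack_labs <- function(labs) do.call(rbind, labs)

#' Prepare image input for repeated forward passes
#'
#' For the transformer encoder this patchifies and flattens every image once
#' (training then reuses the token matrix every epoch); for the convolutional
#' encoder the image arrays are kept as-is.
#'
#' @param model A [cmf_model()].
#' @param images List of preprocessed H x W x channels arrays.
#' @return Opaque input object consumed by [cmf_forward()].
#' @export
prepare_image_input <- function(model, images) {
  if (model$config$image_encoder == "vit") {
    list(type = "vit", B = length(images),
         Xp_flat = images_to_patchflat(images, model$config$patch))
  } else {
    list(type = "conv", B = length(images), images = images)
  }
}

#' Batched forward pass through the full framework
#'
#' Composition: modality encoders -> concatenation -> SmartTrim gate (hard
#' mask, per sample) -> branch split -> cross-modal attention fusion with
#' residual + layer norm (or the linear adapter when fusion is disabled) ->
#' bottleneck prediction head. Deterministic given weights and inputs.
#'
#' @param model A [cmf_model()].
#' @param img_input Output of [prepare_image_input()] (or a list of image
#'   arrays, converted on the fly).
#' @param labs List of preprocessed T x K laboratory matrices.
#' @param keep_cache Keep the intermediate activations needed by
#'   [cmf_backward()]?
#' @return List with `probs` (B x C), `F_I`, `F_L`, `F_cat`, `S`, `tau`,
#'   `mask`, `soft`, `F_prune`, `Attn`, `F_fusion`, `F_refine`, `logits` and
#'   (if `keep_cache`) the activation caches.
#' @export
cmf_forward <- function(model, img_input, labs, keep_cache = FALSE) {
  cf <- model$config; p <- model$params
  if (is.null(img_input$type)) img_input <- prepare_image_input(model, img_input)
  B <- img_input$B
  d <- cf$d

  ## modality encoders
  if (cf$image_encoder == "vit") {
    enc <- vit_fwd(model, img_input$Xp_flat, B)
  } else {
    enc <- conv_fwd(model, img_input$images)
  }
  F_I <- enc$F_I
  L0 <- stack_labs(labs)
  Tn <- nrow(labs[[1]])
  P1 <- linear_fwd(L0, p$lab_W1, p$lab_b1); H1 <- relu(P1)
  P2 <- linear_fwd(H1, p$lab_W2, p$lab_b2); H2 <- relu(P2)
  F_L <- rowsum(H2, rep(seq_len(B), each = Tn)) / Tn
  dimnames(F_L) <- NULL

  F_cat <- cbind(F_I, F_L)

  ## SmartTrim gate
  if (cf$smarttrim) {
    Z <- linear_fwd(F_cat, p$st_W, p$st_b)
    S <- sigmoid(Z)
    mu <- rowMeans(S)
    sdp <- sqrt(rowMeans((S - mu)^2))
    tau <- mu + cf$lambda * sdp
    M <- (S >= tau) * 1
    dead <- rowSums(M) == 0
    if (any(dead))
      M[cbind(which(dead), max.col(S[dead, , drop = FALSE], "first"))] <- 1
    soft <- sigmoid((S - tau) / cf$temperature)
    F_prune <- F_cat * M
  } else {
    Z <- NULL; S <- NULL; tau <- NULL
    M <- matrix(1, B, 2L * d)
    soft <- NULL
    F_prune <- F_cat
  }
  F_pI <- F_prune[, seq_len(d), drop = FALSE]
  F_pL <- F_prune[, d + seq_len(d), drop = FALSE]

  ## fusion
  fus_cache <- NULL
  if (cf$fusion) {
    m <- cf$tokens
    Vf <- F_pL %*% p$f_Wv
    if (m == 1L) {
      Attn <- Vf
      Qf <- NULL; Kf <- NULL; Pl <- NULL
    } else {
      dm <- d %/% m
      Qf <- F_pI %*% p$f_Wq
      Kf <- F_pL %*% p$f_Wk
      Attn <- matrix(0, B, d)
      Pl <- vector("list", B)
      for (b in seq_len(B)) {
        Qt <- t(matrix(Qf[b, ], dm, m))
        Kt <- t(matrix(Kf[b, ], dm, m))
        Vt <- t(matrix(Vf[b, ], dm, m))
        Pm <- softmax_rows(Qt %*% t(Kt) / sqrt(dm))
        Attn[b, ] <- as.vector(t(Pm %*% Vt))
        Pl[[b]] <- Pm
      }
    }
    ln <- layernorm_fwd(Attn + F_pI, p$f_ln_g, p$f_ln_b, cf$ln_eps)
    F_fusion <- ln$y
    fus_cache <- list(Vf = Vf, Qf = Qf, Kf = Kf, P = Pl, ln = ln, Attn = Attn)
  } else {
    Attn <- NULL
    F_fusion <- linear_fwd(F_prune, p$ad_W, p$ad_b)
  }

  ## prediction head
  R1 <- linear_fwd(F_fusion, p$h_Wb, p$h_bb)
  F_refine <- relu(R1)
  logits <- linear_fwd(F_refine, p$h_Wo, p$h_bo)
  probs <- softmax_rows(logits)

  out <- list(probs = probs, logits = logits, F_I = F_I, F_L = F_L,
              F_cat = F_cat, S = S, tau = tau, mask = M, soft = soft,
              F_prune = F_prune, Attn = Attn, F_fusion = F_fusion,
              F_refine = F_refine, B = B)
  if (keep_cache) {
    out$cache <- list(enc = enc, L0 = L0, P1 = P1, H1 = H1, P2 = P2,
                      Tn = Tn, Z = Z, fus = fus_cache, R1 = R1)
  }
  out
}

## ---- full model backward --------------------------------------------------

## Gradient of the training objective w.r.t. every trainable array.
## Straight-through convention at the hard mask: the gradient reaching F_cat
## through the gate uses the hard mask (the true gradient of the forward),
## while the gradient to the scores flows through the sigmoid relaxation
## sigma((S - tau)/temperature) with tau treated as a constant. The sparsity
## term is beta * mean(relaxed mask).
cmf_backward <- function(model, fwd, labels, alpha = 0.1, beta = 0.05) {
  cf <- model$config; p <- model$params
  B <- fwd$B; d <- cf$d
  ca <- fwd$cache
  if (is.null(ca)) stop_cmf("forward pass must be run with keep_cache = TRUE")

  Y <- matrix(0, B, cf$n_classes)
  Y[cbind(seq_len(B), as.integer(labels) + 1L)] <- 1
  pl <- fwd$probs[cbind(seq_len(B), as.integer(labels) + 1L)]
  l_cls <- mean(-log(pmax(pl, 1e-12)))

  g <- list()
  g_logits <- (fwd$probs - Y) / B
  g$h_Wo <- t(fwd$F_refine) %*% g_logits
  g$h_bo <- colSums(g_logits)
  g_Fref <- g_logits %*% t(p$h_Wo)
  g_R1 <- g_Fref * (ca$R1 > 0)
  g$h_Wb <- t(fwd$F_fusion) %*% g_R1
  g$h_bb <- colSums(g_R1)
  g_Ffus <- g_R1 %*% t(p$h_Wb)

  ## fusion backward
  F_pI <- fwd$F_prune[, seq_len(d), drop = FALSE]
  F_pL <- fwd$F_prune[, d + seq_len(d), drop = FALSE]
  if (cf$fusion) {
    fc <- ca$fus
    lb <- layernorm_bwd(g_Ffus, fc$ln, p$f_ln_g)
    g$f_ln_g <- lb$g_g; g$f_ln_b <- lb$g_b
    g_Attn <- lb$gx
    g_FpI <- lb$gx                     # residual branch
    m <- cf$tokens
    if (m == 1L) {
      g$f_Wv <- t(F_pL) %*% g_Attn
      g$f_Wq <- p$f_Wq * 0; g$f_Wk <- p$f_Wk * 0
      g_FpL <- g_Attn %*% t(p$f_Wv)
    } else {
      dm <- d %/% m
      g_Qf <- matrix(0, B, d); g_Kf <- g_Qf; g_Vf <- g_Qf
      for (b in seq_len(B)) {
        Qt <- t(matrix(fc$Qf[b, ], dm, m))
        Kt <- t(matrix(fc$Kf[b, ], dm, m))
        Vt <- t(matrix(fc$Vf[b, ], dm, m))
        Pm <- fc$P[[b]]
        gO <- t(matrix(g_Attn[b, ], dm, m))
        gP <- gO %*% t(Vt)
        gVt <- t(Pm) %*% gO
        gS <- Pm * (gP - rowSums(gP * Pm))
        gQt <- gS %*% Kt / sqrt(dm)
        gKt <- t(gS) %*% Qt / sqrt(dm)
        g_Qf[b, ] <- as.vector(t(gQt))
        g_Kf[b, ] <- as.vector(t(gKt))
        g_Vf[b, ] <- as.vector(t(gVt))
      }
      g$f_Wq <- t(F_pI) %*% g_Qf
      g$f_Wk <- t(F_pL) %*% g_Kf
      g$f_Wv <- t(F_pL) %*% g_Vf
      g_FpI <- g_FpI + g_Qf %*% t(p$f_Wq)
      g_FpL <- g_Kf %*% t(p$f_Wk) + g_Vf %*% t(p$f_Wv)
    }
    g_Fprune <- cbind(g_FpI, g_FpL)
  } else {
    g$ad_W <- t(fwd$F_prune) %*% g_Ffus
    g$ad_b <- colSums(g_Ffus)
    g_Fprune <- g_Ffus %*% t(p$ad_W)
  }

  ## SmartTrim backward (straight-through)
  l_sparse <- 0
  if (cf$smarttrim) {
    soft <- fwd$soft
    l_sparse <- mean(soft)
    g_Fcat <- g_Fprune * fwd$mask
    g_soft <- g_Fprune * fwd$F_cat + beta / (B * 2 * d)
    g_S <- g_soft * soft * (1 - soft) / cf$temperature
    g_Z <- g_S * fwd$S * (1 - fwd$S)
    g$st_W <- t(fwd$F_cat) %*% g_Z
    g$st_b <- colSums(g_Z)
    g_Fcat <- g_Fcat + g_Z %*% t(p$st_W)
  } else {
    g_Fcat <- g_Fprune
  }
  g_FI <- g_Fcat[, seq_len(d), drop = FALSE]
  g_FL <- g_Fcat[, d + seq_len(d), drop = FALSE]

  ## alignment loss: L_cm = mean over samples of 1 - cos(F_I, F_L)
  l_cm <- 0
  for (b in seq_len(B)) {
    u <- fwd$F_I[b, ]; v <- fwd$F_L[b, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) {      # undefined direction: no gradient
      l_cm <- l_cm + 1
      next
    }
    cs <- sum(u * v) / (nu * nv)
    l_cm <- l_cm + (1 - cs)
    g_FI[b, ] <- g_FI[b, ] - (alpha / B) * (v / (nu * nv) - cs * u / nu^2)
    g_FL[b, ] <- g_FL[b, ] - (alpha / B) * (u / (nu * nv) - cs * v / nv^2)
  }
  l_cm <- l_cm / B

  ## laboratory encoder backward
  g_H2 <- g_FL[rep(seq_len(B), each = ca$Tn), , drop = FALSE] / ca$Tn
  g_P2 <- g_H2 * (ca$P2 > 0)
  g$lab_W2 <- t(ca$H1) %*% g_P2
  g$lab_b2 <- colSums(g_P2)
  g_H1 <- g_P2 %*% t(p$lab_W2)
  g_P1 <- g_H1 * (ca$P1 > 0)
  g$lab_W1 <- t(ca$L0) %*% g_P1
  g$lab_b1 <- colSums(g_P1)

  ## image encoder backward
  if (cf$image_encoder == "vit") {
    g <- c(g, vit_bwd(model, ca$enc, g_FI))
  } else {
    g <- c(g, conv_bwd(model, ca$enc, g_FI))
  }

  loss <- list(cls = l_cls, cm = l_cm, sparse = l_sparse,
               total = l_cls + alpha * l_cm + beta * l_sparse)
  list(grads = g, loss = loss)
}

## ---- optimizer and schedule -----------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

## Decoupled-weight-decay adaptive moments update. Weight decay applies to
## weight matrices only (1-d arrays: biases, norm affines, tokens are exempt).
adamw_step <- function(params, grads, state, trainable, lr,
                       beta1 = 0.9, beta2 = 0.999, wd = 1e-5, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (!trainable[[nm]] || is.null(grads[[nm]])) next
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (!is.null(dim(params[[nm]])))
      upd <- upd + wd * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Learning-rate schedule: linear warmup then cosine annealing
#'
#' Epochs `0 .. warmup-1` ramp linearly from `lr_init/warmup` up to the peak
#' `lr_init`; epochs `warmup .. epochs-1` follow cosine annealing from
#' `lr_init` down to `lr_final` at the last epoch.
#'
#' @param epoch Zero-based epoch index.
#' @param epochs Total number of epochs.
#' @param warmup Warmup epochs (default 5).
#' @param lr_init Peak learning rate (default 1e-4).
#' @param lr_final Final learning rate (default 1e-6).
#' @export
lr_schedule <- function(epoch, epochs, warmup = 5L, lr_init = 1e-4,
                        lr_final = 1e-6) {
  if (epoch < warmup) return(lr_init * (epoch + 1) / warmup)
  if (epochs - 1L <= warmup) return(lr_final)
  prog <- (epoch - warmup) / (epochs - 1L - warmup)
  lr_final + 0.5 * (lr_init - lr_final) * (1 + cos(pi * prog))
}

## ---- accounting -----------------------------------------------------------

#' Count trainable parameters
#'
#' For a `cmf_model`, sums the element counts of arrays flagged trainable
#' (frozen arrays are excluded); for a plain list of arrays, sums everything.
#'
#' @param x A `cmf_model` or a list of numeric arrays.
#' @return Integer-valued count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "cmf_model")) {
    sum(vapply(names(x$params), function(nm)
      if (x$trainable[[nm]]) length(x$params[[nm]]) else 0L, numeric(1)))
  } else {
    sum(vapply(x, length, numeric(1)))
  }
}

#' Estimate forward-pass floating-point operations
#'
#' Counts 2 FLOPs per multiply-accumulate plus one add per bias element,
#' layer by layer, on the configured input resolution (overridable). Layer
#' norms, activations and softmaxes are excluded from the count (the
#' convention of the usual MAC-counting tools, doubled to FLOPs).
#'
#' @param model A [cmf_model()].
#' @param input_size Optional `c(H, W)` overriding the configured image size.
#' @param batch Batch size multiplier (default 1).
#' @param breakdown Return the per-layer table instead of the total?
#' @return Total FLOP count, or a data frame with columns `layer`, `flops`.
#' @export
estimate_flops <- function(model, input_size = NULL, batch = 1,
                           breakdown = FALSE) {
  cf <- model$config
  d <- cf$d
  H <- if (is.null(input_size)) cf$image_size[1] else input_size[1]
  W <- if (is.null(input_size)) cf$image_size[2] else input_size[2]
  CH <- cf$image_size[3]
  rows <- list()
  add <- function(layer, flops) rows[[length(rows) + 1L]] <<-
    data.frame(layer = layer, flops = flops)
  lin <- function(n_in, n_out, times = 1) times * (2 * n_in * n_out + n_out)
  if (cf$image_encoder == "vit") {
    N <- (H %/% cf$patch) * (W %/% cf$patch)
    S <- N + 1
    ppc <- cf$patch^2 * CH
    add("patch_embed", lin(ppc, d, N))
    for (i in seq_len(cf$depth)) {
      dff <- round(d * cf$mlp_ratio)
      add(sprintf("block%d_qkv_out", i), lin(d, d, 4 * S))
      add(sprintf("block%d_attention", i), 2 * (2 * S * S * d))
      add(sprintf("block%d_mlp", i), lin(d, dff, S) + lin(dff, d, S))
    }
  } else {
    hh <- H; ww <- W
    chans <- c(CH, cf$conv_channels)
    for (l in 1:3) {
      add(sprintf("conv%d", l), lin(9 * chans[l], chans[l + 1], hh * ww))
      hh <- hh %/% 2; ww <- ww %/% 2
    }
    add("conv_proj", lin(chans[4], d))
  }
  add("lab_mlp", lin(cf$K, cf$lab_hidden, cf$T_steps) +
        lin(cf$lab_hidden, d, cf$T_steps))
  if (cf$smarttrim) add("smarttrim_scorer", lin(2 * d, 2 * d))
  if (cf$fusion) {
    m <- cf$tokens
    if (m == 1L) {
      add("fusion_value_proj", 2 * d * d)
    } else {
      add("fusion_qkv", 3 * 2 * d * d)
      add("fusion_attention", 2 * (2 * m * m * (d / m)))
    }
  } else {
    add("fusion_adapter", lin(2 * d, d))
  }
  add("head", lin(d, cf$head_hidden) + lin(cf$head_hidden, cf$n_classes))
  tab <- do.call(rbind, rows)
  tab$flops <- tab$flops * batch
  if (breakdown) tab else sum(tab$flops)
}
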