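## Cross-modal attention fusion and prediction head. Queries come from the
## (gated) image branch, keys and values from the laboratory branch; the
## attention output is residual-connected to the image branch and layer
## normalized, then classified through a bottleneck head.

#' Cross-modal scaled dot-product attention
#'
#' `Q = W_Q . F_I', K = W_K . F_L', V = W_V . F_L'`, then
#' `softmax(Q K^T / sqrt(d_token)) V`. In the default vector mode
#' (`tokens = 1`) the softmax is over a single key and the output equals
#' `W_V . F_L'` exactly. With `tokens = m > 1` each projected vector is
#' reshaped into `m` tokens of dimension `d/m` (contiguous chunks) and
#' standard attention runs across tokens, the output re-flattened to length
#' d.
#'
#' @param f_prune_i,f_prune_l Gated branch features, length d each.
#' @param weights List with d x d matrices `W_q`, `W_k`, `W_v` (row-vector
#'   convention: the feature multiplies on the left).
#' @param tokens Tokens per branch (`d` must be divisible).
#' @return Length-d attention output.
#' @export
cross_modal_attention <- function(f_prune_i, f_prune_l, weights,
                                  tokens = 1L) {
  d <- length(f_prune_i)
  if (length(f_prune_l) != d) stop_cmf("branch feature length mismatch")
  for (nm in c("W_q", "W_k", "W_v"))
    if (!all(dim(weights[[nm]]) == c(d, d)))
      stop_cmf(sprintf("'%s' must be %d x %d", nm, d, d))
  if (d %% tokens != 0) stop_cmf("'d' must be divisible by 'tokens'")
  v <- drop(f_prune_l %*% weights$W_v)
  if (tokens == 1L) return(v)
  m <- tokens; dm <- d %/% m
  Qt <- t(matrix(drop(f_prune_i %*% weights$W_q), dm, m))
  Kt <- t(matrix(drop(f_prune_l %*% weights$W_k), dm, m))
  Vt <- t(matrix(v, dm, m))
  Pm <- softmax_rows(Qt %*% t(Kt) / sqrt(dm))
  as.vector(t(Pm %*% Vt))
}

#' Residual connection plus layer normalization
#'
#' `F_fusion = LayerNorm(Attn + F_prune_I)` over the d entries, with
#' learnable gain/bias (identity at initialization) and an epsilon-stabilized
#' standard deviation. With unit gain and zero bias the output has mean 0 and
#' variance ~1 (exactly 0 for a zero input vector).
#'
#' @param attn Attention output, length d.
#' @param f_prune_i Gated image branch, length d.
#' @param gain,bias Affine parameters (defaults: identity).
#' @param eps Stabilizer added to the variance (default 1e-5).
#' @return Length-d fused feature.
#' @export
fuse_residual_norm <- function(attn, f_prune_i, gain = rep(1, length(attn)),
                               bias = numeric(length(attn)), eps = 1e-5) {
  if (length(attn) != length(f_prune_i)) stop_cmf("length mismatch")
  x <- attn + f_prune_i
  mu <- mean(x)
  v <- mean((x - mu)^2)
  drop((x - mu) / sqrt(v + eps)) * gain + bias
}

#' Bottleneck prediction head
#'
#' `F_refine = ReLU(W_b . F_fusion + b_b)` (dimension d/2), then class
#' probabilities `softmax(W_o . F_refine + b_o)`.
#'
#' @param f_fusion Fused feature, length d.
#' @param weights List with `W_b` (d x d/2), `b_b`, `W_o` (d/2 x C), `b_o`.
#' @return List with `f_refine` and `probs` (length C, on the simplex).
#' @export
predict_head <- function(f_fusion, weights) {
  C <- ncol(weights$W_o)
  if (C < 2) stop_cmf("need at least 2 classes")
  f_refine <- relu(drop(f_fusion %*% weights$W_b) + weights$b_b)
  logits <- drop(f_refine %*% weights$W_o) + weights$b_o
  list(f_refine = f_refine,
       probs = drop(softmax_rows(matrix(logits, 1L))))
}

#' Full forward pass for a single sample
#'
#' Runs the deterministic composition encode -> concatenate -> SmartTrim
#' gate -> branch split -> attention fusion (or the linear adapter when
#' fusion is disabled) -> prediction head, returning every intermediate
#' state. Ablation toggles in the model's config are respected: with the
#' gate disabled `F_prune == F_cat`, with fusion disabled the head consumes
#' the gated concatenation through the 2d -> d adapter.
#'
#' @param sample List with `image` (preprocessed array) and `lab`
#'   (preprocessed T x K matrix), e.g. one element of a prepared split.
#' @param model A [cmf_model()].
#' @return List with `features` (`f_i`, `f_l`, `f_cat`), `pruning` (`scores`,
#'   `tau`, `lambda`, `mask`, `f_prune` and the two branch views) and
#'   `fusion` (`attn`, `f_fusion`, `f_refine`, `probs`).
#' @export
forward_full <- function(sample, model) {
  img <- sample$image
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  fwd <- cmf_forward(model, prepare_image_input(model, list(img)),
                     list(as.matrix(sample$lab)))
  d <- model$config$d
  list(
    features = list(f_i = drop(fwd$F_I), f_l = drop(fwd$F_L),
                    f_cat = drop(fwd$F_cat)),
    pruning = list(scores = if (!is.null(fwd$S)) drop(fwd$S),
                   tau = if (!is.null(fwd$tau)) drop(fwd$tau),
                   lambda = model$config$lambda,
                   mask = drop(fwd$mask),
                   f_prune = drop(fwd$F_prune),
                   image = drop(fwd$F_prune)[seq_len(d)],
                   lab = drop(fwd$F_prune)[d + seq_len(d)]),
    fusion = list(attn = if (!is.null(fwd$Attn)) drop(fwd$Attn),
                  f_fusion = drop(fwd$F_fusion),
                  f_refine = drop(fwd$F_refine),
                  probs = drop(fwd$probs))
  )
}
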