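## Modality encoders: patch tokenization + transformer for images, two-layer
## MLP with temporal mean pooling for laboratory series. Both map to the
## shared embedding dimension d ("preliminary alignment").

#' Split an image into non-overlapping square patches
#'
#' Patches are ordered row-major from the top-left origin (all patches of the
#' first patch-row first). [unpatchify()] inverts the operation bit-exactly.
#'
#' @param image H x W x channels array (a matrix is treated as one channel).
#' @param P Patch size in pixels; `H` and `W` must be divisible by it.
#' @return Array of shape `(N, P, P, channels)` with `N = (H/P) * (W/P)`.
#' @export
patchify <- function(image, P) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (d[1] %% P != 0)
    stop_cmf(sprintf("image height %d not divisible by patch size %d", d[1], P))
  if (d[2] %% P != 0)
    stop_cmf(sprintf("image width %d not divisible by patch size %d", d[2], P))
  nh <- d[1] %/% P; nw <- d[2] %/% P
  out <- array(0, c(nh * nw, P, P, d[3]))
  n <- 0L
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      n <- n + 1L
      out[n, , , ] <- image[((i - 1L) * P + 1L):(i * P),
                            ((j - 1L) * P + 1L):(j * P), , drop = FALSE]
    }
  }
  out
}

#' Reassemble an image from its patch sequence
#'
#' @param patches Array from [patchify()].
#' @param H,W Original image height and width.
#' @return H x W x channels array equal to the original image.
#' @export
unpatchify <- function(patches, H, W) {
  P <- dim(patches)[2]
  CH <- dim(patches)[4]
  nh <- H %/% P; nw <- W %/% P
  img <- array(0, c(H, W, CH))
  n <- 0L
  for (i in seq_len(nh)) {
    for (j in seq_len(nw)) {
      n <- n + 1L
      img[((i - 1L) * P + 1L):(i * P), ((j - 1L) * P + 1L):(j * P), ] <-
        patches[n, , , ]
    }
  }
  img
}

#' Linearly embed patches, prepend the class token, add position embeddings
#'
#' Each patch is flattened (column-major over its `P x P x channels` block)
#' and mapped through `patch_W` (+ `patch_b`); the learnable class token is
#' prepended as row 1 and the learnable position embedding added elementwise.
#'
#' @param patches Array from [patchify()].
#' @param weights List with `patch_W` (`P*P*channels` x d), `patch_b`
#'   (length d), `cls` (length d) and `pos` (`(N+1)` x d).
#' @return `(N+1)` x d embedded token matrix; row 1 is the class token.
#' @export
embed_patches <- function(patches, weights) {
  N <- dim(patches)[1]
  flat <- matrix(aperm(patches, c(2, 3, 4, 1)), N, byrow = TRUE)
  if (ncol(flat) != nrow(weights$patch_W) ||
      nrow(weights$pos) != N + 1L ||
      length(weights$cls) != ncol(weights$patch_W))
    stop_cmf("embedding weight shapes do not match the patch sequence")
  X <- linear_fwd(flat, weights$patch_W, weights$patch_b)
  emb <- rbind(matrix(weights$cls, 1L), X) + weights$pos
  dimnames(emb) <- NULL
  emb
}

#' Encode an image into its d-dimensional semantic feature
#'
#' Patch tokenization, linear embedding with class token and position
#' embeddings, `depth` pre-norm transformer blocks (multi-head self-attention
#' and GELU feed-forward, both with residual connections), returning the
#' final state of the class token.
#'
#' @param image Preprocessed image of the configured size.
#' @param model A [cmf_model()] with `image_encoder = "vit"` (its config and
#'   weights are used).
#' @return Length-d numeric vector `F_I`.
#' @export
encode_image <- function(image, model) {
  if (model$config$image_encoder != "vit")
    stop_cmf("encode_image requires a transformer image encoder")
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  flat <- images_to_patchflat(list(image), model$config$patch)
  drop(vit_fwd(model, flat, 1L)$F_I)
}

#' Encode a laboratory time series into its d-dimensional feature
#'
#' Per time step: `ReLU(W2 . ReLU(W1 . x + b1) + b2)`, then mean pooling over
#' the `T` axis. The outer ReLU makes every entry of `F_L` nonnegative.
#'
#' @param series T x K matrix in `[0, 1]`.
#' @param model A [cmf_model()] (its `lab_*` weights are used), or a list
#'   with `lab_W1` (K x d/2), `lab_b1`, `lab_W2` (d/2 x d), `lab_b2`.
#' @return Length-d nonnegative numeric vector `F_L`.
#' @export
encode_lab <- function(series, model) {
  p <- if (inherits(model, "cmf_model")) model$params else model
  series <- as.matrix(series)
  if (ncol(series) != nrow(p$lab_W1))
    stop_cmf(sprintf("series has %d features but lab_W1 expects %d",
                     ncol(series), nrow(p$lab_W1)))
  H1 <- relu(linear_fwd(series, p$lab_W1, p$lab_b1))
  H2 <- relu(linear_fwd(H1, p$lab_W2, p$lab_b2))
  colMeans(H2)
}
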