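## SmartTrim dynamic feature pruning: sigmoid importance scores on the
## concatenated bimodal feature, adaptive threshold tau = mean + lambda*std,
## binary mask, elementwise gating, and the branch split consumed by fusion.

#' Importance scores for the concatenated bimodal feature
#'
#' `S = sigmoid(F_cat %*% W_s + b_s)` with a dimension-preserving single
#' linear layer (`W_s` is 2d x 2d), so every feature dimension receives its
#' own score in `(0, 1)`.
#'
#' @param f_cat Length-2d numeric vector (the concatenation `[F_I; F_L]`).
#' @param W_s 2d x 2d weight matrix (input dim x output dim; the feature
#'   vector multiplies on the left as a row vector).
#' @param b_s Length-2d bias.
#' @return Length-2d score vector in `(0, 1)`.
#' @export
importance_scores <- function(f_cat, W_s, b_s = numeric(ncol(W_s))) {
  if (length(f_cat) != nrow(W_s) || nrow(W_s) != ncol(W_s) ||
      length(b_s) != ncol(W_s))
    stop_cmf("scorer weight shape mismatch: need square W_s matching length(f_cat)")
  as.numeric(sigmoid(drop(f_cat %*% W_s) + b_s))
}

#' Dynamic pruning threshold
#'
#' `tau = mean(S) + lambda * std(S)` where `std` is the population standard
#' deviation (divide by the number of entries) over this sample's score
#' vector.
#'
#' @param s Score vector.
#' @param lambda Nonnegative threshold coefficient (default 0.3).
#' @return The scalar threshold `tau`.
#' @export
dynamic_threshold <- function(s, lambda = 0.3) {
  if (length(s) == 0) stop_cmf("'s' must be nonempty")
  check_number(lambda, "lambda", lower = 0)
  mean(s) + lambda * pop_sd(s)
}

#' Binary pruning mask
#'
#' `M_j = 1` iff `S_j >= tau` (inclusive). If the rule retains nothing (which
#' happens when `(max(S) - mean(S)) / std(S) < lambda`), the single
#' largest-score entry is kept, ties broken by lowest index, so the gated
#' feature can never collapse to the zero vector.
#'
#' @param s Score vector.
#' @param tau Threshold from [dynamic_threshold()].
#' @return Numeric 0/1 vector of `length(s)` with `sum >= 1`.
#' @export
build_mask <- function(s, tau) {
  m <- as.numeric(s >= tau)
  if (sum(m) == 0) m[which.max(s)] <- 1
  m
}

#' Apply a pruning mask elementwise
#'
#' @param f_cat Feature vector.
#' @param m 0/1 mask of the same length.
#' @return `f_cat * m`; masked entries are exactly zero.
#' @export
apply_mask <- function(f_cat, m) {
  if (length(f_cat) != length(m)) stop_cmf("mask/feature length mismatch")
  f_cat * m
}

#' Split a gated concatenated feature into its modality branches
#'
#' The first `d` entries are the image branch, the last `d` the laboratory
#' branch, matching the `[F_I; F_L]` concatenation order.
#'
#' @param f_prune Length-2d vector.
#' @param d Branch dimension; defaults to `length(f_prune) / 2`, which must
#'   then be an integer.
#' @return List with `image` and `lab` length-d vectors.
#' @export
split_branches <- function(f_prune, d = NULL) {
  if (is.null(d)) {
    if (length(f_prune) %% 2 != 0)
      stop_cmf("odd-length input: supply 'd' explicitly")
    d <- length(f_prune) %/% 2
  }
  if (length(f_prune) != 2 * d) stop_cmf("'f_prune' must have length 2*d")
  list(image = f_prune[seq_len(d)], lab = f_prune[d + seq_len(d)])
}

#' Full SmartTrim gating of one concatenated feature vector
#'
#' Convenience composition of [importance_scores()], [dynamic_threshold()],
#' [build_mask()], [apply_mask()] and [split_branches()].
#'
#' @inheritParams importance_scores
#' @inheritParams dynamic_threshold
#' @return A list of class `cmf_pruning_state` with fields `scores`,
#'   `lambda`, `tau`, `mask`, `f_prune`, `image`, `lab`.
#' @export
smarttrim_gate <- function(f_cat, W_s, b_s = numeric(ncol(W_s)),
                           lambda = 0.3) {
  s <- importance_scores(f_cat, W_s, b_s)
  tau <- dynamic_threshold(s, lambda)
  m <- build_mask(s, tau)
  fp <- apply_mask(f_cat, m)
  br <- split_branches(fp)
  structure(list(scores = s, lambda = lambda, tau = tau, mask = m,
                 f_prune = fp, image = br$image, lab = br$lab),
            class = "cmf_pruning_state")
}
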