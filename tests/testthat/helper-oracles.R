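# Independent brute-force oracles. Deliberately written as plain loops over
# definitions, sharing no code with the package internals they check.

oracle_threshold <- function(s, lambda) {
  n <- length(s)
  m <- sum(s) / n
  v <- 0
  for (x in s) v <- v + (x - m)^2
  m + lambda * sqrt(v / n)
}

oracle_mask <- function(s, tau) {
  m <- numeric(length(s))
  for (j in seq_along(s)) if (s[j] >= tau) m[j] <- 1
  if (sum(m) == 0) {
    best <- 1
    for (j in seq_along(s)) if (s[j] > s[best]) best <- j
    m[best] <- 1
  }
  m
}

oracle_sparsity <- function(f) {
  z <- 0
  for (x in f) if (x == 0) z <- z + 1
  100 * z / length(f)
}

oracle_cosine <- function(u, v) {
  num <- 0; nu <- 0; nv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  num / sqrt(nu * nv)
}

oracle_accuracy <- function(cm) {
  sum(diag(cm)) / sum(cm)
}

oracle_f1_macro <- function(cm) {
  C <- nrow(cm)
  f1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    f1[c] <- if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      2 * p * r / (p + r)
    }
  }
  mean(f1)
}

oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- 0
  for (c in seq_len(nrow(cm))) pe <- pe + sum(cm[c, ]) * sum(cm[, c])
  pe <- pe / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

# Pairwise enumeration of the rank statistic, ties counted one half.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Trapezoidal integration of the empirical ROC curve (threshold sweep).
oracle_auc_trapezoid <- function(scores, positive) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0); fpr <- c(0)
  np <- sum(positive); nn <- sum(!positive)
  for (t in th) {
    tpr <- c(tpr, sum(scores[positive] >= t) / np)
    fpr <- c(fpr, sum(scores[!positive] >= t) / nn)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Step-by-step recomputation of a one-block, one-head transformer encoder
# on an embedded token matrix (pre-norm, GELU feed-forward, residuals),
# returning the class-token row.
oracle_tiny_transformer <- function(X_emb, w, eps = 1e-5) {
  ln <- function(x, g, b) {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    (x - mu) / sqrt(v + eps) * g + b
  }
  S <- nrow(X_emb); d <- ncol(X_emb)
  Xn <- t(apply(X_emb, 1, ln, g = w$ln1_g, b = w$ln1_b))
  Q <- Xn %*% w$Wq + matrix(w$bq, S, d, byrow = TRUE)
  K <- Xn %*% w$Wk + matrix(w$bk, S, d, byrow = TRUE)
  V <- Xn %*% w$Wv + matrix(w$bv, S, d, byrow = TRUE)
  A <- matrix(0, S, d)
  for (i in seq_len(S)) {
    sc <- numeric(S)
    for (j in seq_len(S)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
    p <- exp(sc - max(sc)); p <- p / sum(p)
    for (j in seq_len(S)) A[i, ] <- A[i, ] + p[j] * V[j, ]
  }
  AO <- A %*% w$Wo + matrix(w$bo, S, d, byrow = TRUE)
  Xmid <- X_emb + AO
  Xn2 <- t(apply(Xmid, 1, ln, g = w$ln2_g, b = w$ln2_b))
  H <- Xn2 %*% w$W1 + matrix(w$b1, S, length(w$b1), byrow = TRUE)
  Hg <- H * pnorm(H)
  FF <- Hg %*% w$W2 + matrix(w$b2, S, d, byrow = TRUE)
  (Xmid + FF)[1, ]
}
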