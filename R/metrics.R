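## Evaluation metrics and the three-term training objective.

#' Three-term training objective
#'
#' `L_total = L_cls + alpha * L_cm + beta * L_sparse` where `L_cls` is the
#' batch-mean cross-entropy `-log(Yhat[label])` (probabilities clamped at
#' 1e-12 before the log), `L_cm = 1 - cos(F_I, F_L)` (batch-meaned) pulls the
#' modality embeddings together, and `L_sparse` is the mean of the supplied
#' mask entries (during training the sigmoid-relaxed mask, for reporting the
#' hard mask).
#'
#' @param probs Probability vector (one sample) or matrix with one row per
#'   sample, rows on the simplex.
#' @param labels Integer labels in `[0, C)`.
#' @param f_i,f_l Modality embeddings: length-d vectors or matrices with one
#'   row per sample.
#' @param mask Mask vector or matrix (entries in `[0, 1]`).
#' @param alpha Weight of the alignment term (default 0.1).
#' @param beta Weight of the sparsity term (default 0.05).
#' @return List of class `cmf_loss` with `cls`, `cm`, `sparse`, `alpha`,
#'   `beta`, `total`; `total` is computed as `cls + alpha * cm + beta *
#'   sparse` in that order.
#' @export
loss_total <- function(probs, labels, f_i, f_l, mask, alpha = 0.1,
                       beta = 0.05) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (is.null(dim(f_i))) f_i <- matrix(f_i, nrow = 1)
  if (is.null(dim(f_l))) f_l <- matrix(f_l, nrow = 1)
  B <- nrow(probs)
  if (length(labels) != B) stop_cmf("labels/probs size mismatch")
  p <- probs[cbind(seq_len(B), as.integer(labels) + 1L)]
  l_cls <- mean(-log(pmax(p, 1e-12)))
  cms <- vapply(seq_len(B), function(i)
    cross_modal_similarity(f_i[i, ], f_l[i, ]), numeric(1))
  l_cm <- mean(1 - cms)
  l_sparse <- mean(mask)
  structure(list(cls = l_cls, cm = l_cm, sparse = l_sparse,
                 alpha = alpha, beta = beta,
                 total = l_cls + alpha * l_cm + beta * l_sparse),
            class = "cmf_loss")
}

#' Accuracy from confusion counts
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return `(tp + tn) / (tp + tn + fp + fn)`.
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  if (tot <= 0) stop_cmf("zero total count")
  (tp + tn) / tot
}

#' F1 score from confusion counts
#'
#' Harmonic mean of precision `tp/(tp+fp)` and recall `tp/(tp+fn)`; defined
#' as 0 when `tp = 0` (the usual convention for an absent class).
#' @param tp,fp,fn Nonnegative counts.
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (P_o - P_e) / (1 - P_e)` with observed agreement `P_o =
#' trace/total` and expected agreement `P_e = sum_c row_c * col_c / total^2`.
#' Returns 1 in the degenerate `P_e = 1` case (all mass in one cell).
#'
#' @param cm Square nonnegative matrix, rows = truth, columns = prediction.
#' @export
kappa_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) stop_cmf("'cm' must be square and nonnegative")
  n <- sum(cm)
  if (n <= 0) stop_cmf("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

auc_binary <- function(scores, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0 || nn == 0) stop_cmf("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the ROC curve
#'
#' Computed as the rank (Mann--Whitney) statistic: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties counted
#' one half. For more than two classes, `scores` must be a matrix with one
#' column per class and the macro (unweighted) mean of the one-vs-rest AUCs
#' over the classes present in `labels` is returned.
#'
#' @param scores Numeric vector (binary: score of the positive class) or
#'   n x C matrix of per-class scores.
#' @param labels Binary 0/1 vector, or integer labels in `[0, C)` when
#'   `scores` is a matrix.
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.null(dim(scores))) {
    pos <- labels == 1 | labels == TRUE
    if (all(pos) || all(!pos))
      stop_cmf("AUC undefined: both classes must be present")
    return(auc_binary(scores, pos))
  }
  labels <- as.integer(labels)
  present <- sort(unique(labels))
  if (length(present) < 2) stop_cmf("AUC undefined: need at least two classes")
  mean(vapply(present, function(cl)
    auc_binary(scores[, cl + 1L], labels == cl), numeric(1)))
}

#' Feature sparsity in percent
#'
#' `100 * (#entries - #nonzero entries) / #entries`; "nonzero" means exactly
#' different from zero (mask-induced zeros are exact). A matrix is treated as
#' a batch and the percentage is taken over all entries.
#'
#' @param f Numeric vector or matrix.
#' @export
feature_sparsity <- function(f) {
  if (length(f) == 0) stop_cmf("'f' must be nonempty")
  100 * sum(f == 0) / length(f)
}

#' Cosine similarity between the two modality embeddings
#'
#' @param f_i,f_l Nonzero numeric vectors of equal length.
#' @return `f_i . f_l / (||f_i|| * ||f_l||)` in `[-1, 1]`.
#' @export
cross_modal_similarity <- function(f_i, f_l) {
  ni <- sqrt(sum(f_i^2))
  nl <- sqrt(sum(f_l^2))
  if (ni == 0 || nl == 0)
    stop_cmf("cosine similarity undefined for a zero vector")
  min(max(sum(f_i * f_l) / (ni * nl), -1), 1)
}

#' Confusion matrix from predictions
#'
#' @param pred,truth Integer labels in `[0, C)`.
#' @param n_classes Number of classes `C`.
#' @return C x C integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(pred, truth, n_classes) {
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(pred))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

# Per-class one-vs-rest counts from a confusion matrix.
class_counts <- function(cm) {
  n <- sum(cm)
  data.frame(
    class = seq_len(nrow(cm)) - 1L,
    tp = diag(cm),
    fp = colSums(cm) - diag(cm),
    fn = rowSums(cm) - diag(cm),
    tn = n - rowSums(cm) - colSums(cm) + diag(cm)
  )
}

#' Macro-averaged F1 from a confusion matrix
#' @param cm Confusion matrix (rows = truth).
#' @export
f1_macro_from_confusion <- function(cm) {
  cc <- class_counts(cm)
  mean(mapply(f1_from_counts, cc$tp, cc$fp, cc$fn))
}
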