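## Data preparation, training loop (AdamW + warmup/cosine schedule + early
## stopping on validation macro F1), and evaluation reports.

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: batch 32, peak learning
#' rate 1e-4 decaying to 1e-6 by cosine annealing after 5 linear warmup
#' epochs, AdamW moments (0.9, 0.999) with decoupled weight decay 1e-5, and
#' early stopping with patience 10 on validation macro F1. `epochs` defaults
#' to the desk-scale 30 (the full recipe uses 100).
#'
#' @param batch_size Mini-batch size.
#' @param lr_init,lr_final,warmup See [lr_schedule()]. `warmup = NULL` (the
#'   default) uses 5 epochs, shrunk to `epochs - 1` for very short runs.
#' @param beta1,beta2,weight_decay AdamW parameters.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation macro
#'   F1 improvement).
#' @param alpha,beta Loss weights of the alignment and sparsity terms.
#' @param seed Run seed: drives initialization and data order.
#' @param verbose Print per-epoch progress?
#' @return List of class `cmf_train_config`.
#' @export
train_config <- function(batch_size = 32L, lr_init = 1e-4, lr_final = 1e-6,
                         warmup = NULL, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-5, epochs = 30L, patience = 10L,
                         alpha = 0.1, beta = 0.05, seed = 1L,
                         verbose = FALSE) {
  if (is.null(warmup)) warmup <- min(5L, as.integer(epochs) - 1L)
  if (warmup >= epochs) stop_cmf("'warmup' must be smaller than 'epochs'")
  if (lr_init <= 0 || lr_final <= 0) stop_cmf("learning rates must be positive")
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_final = lr_final, warmup = as.integer(warmup),
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 alpha = alpha, beta = beta, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "cmf_train_config")
}

#' Split a dataset and preprocess both modalities with frozen training stats
#'
#' Stratified split, per-image z-score standardization (with optional
#' train-split augmentation), and the laboratory pipeline (3-sigma outlier
#' masking, median imputation, min--max scaling, temporal interpolation) with
#' statistics computed on the training split only.
#'
#' @param dataset A `cmf_dataset`.
#' @param config A [cmf_config()] (target image size and `T_steps` come from
#'   here).
#' @param ratios Split proportions (default `c(0.7, 0.2, 0.1)`).
#' @param seed Seed for the split (and augmentation draws).
#' @param augment Apply random augmentation to the training images?
#' @param split Optional precomputed split (list of index vectors), e.g. a
#'   cross-validation fold; overrides `ratios`/`seed` for membership.
#' @return List of class `cmf_prepared` with `train`, `val`, `test` (each
#'   `images`, `labs`, `labels`, `idx`) and the frozen `stats`.
#' @export
cmf_prepare <- function(dataset, config, ratios = c(0.7, 0.2, 0.1),
                        seed = 1L, augment = FALSE, split = NULL) {
  if (is.null(split)) split <- stratified_split(dataset, ratios, seed)
  labels <- dataset_labels(dataset)
  stats <- lab_stats(lapply(dataset$samples[split$train], `[[`, "lab"))
  tsz <- config$image_size[1:2]
  mk <- function(idx, train_mode) {
    imgs <- vector("list", length(idx))
    for (i in seq_along(idx)) {
      imgs[[i]] <- preprocess_image(
        dataset$samples[[idx[i]]]$image, target_size = tsz,
        train_mode = train_mode,
        seed = if (train_mode) derive_seed(seed, 5000L + idx[i]) else NULL)
    }
    labs <- lapply(dataset$samples[idx], function(s)
      preprocess_lab(s$lab, stats, T_target = config$T_steps))
    list(images = imgs, labs = labs, labels = labels[idx], idx = idx)
  }
  structure(list(train = mk(split$train, augment),
                 val = mk(split$val, FALSE),
                 test = if (length(split$test)) mk(split$test, FALSE),
                 stats = stats, config = config),
            class = "cmf_prepared")
}

#' Train the full model
#'
#' Xavier-initialized weights, AdamW with decoupled weight decay, linear
#' warmup followed by cosine annealing, early stopping restoring the weights
#' of the best validation macro F1 epoch. Data order is reshuffled each epoch
#' from seeds derived deterministically from the run seed, so identical
#' seeds give bit-identical histories.
#'
#' @param prepared A [cmf_prepare()] object (train and val splits are used).
#' @param config A [cmf_config()]; defaults to the one stored in `prepared`.
#' @param tc A [train_config()].
#' @return List of class `cmf_fit`: `model` (best weights), `history` (one
#'   row per epoch), `best_epoch`, `best_val_f1`, `config`, `train_config`.
#' @export
cmf_train <- function(prepared, config = prepared$config,
                      tc = train_config()) {
  model <- cmf_model(config, seed = derive_seed(tc$seed, 1L))
  n <- length(prepared$train$labels)
  if (n == 0 || length(prepared$val$labels) == 0)
    stop_cmf("train and val splits must be non-empty")
  full_input <- prepare_image_input(model, prepared$train$images)
  val_input <- prepare_image_input(model, prepared$val$images)
  N <- config$n_patches
  opt <- adamw_init(model$params)
  best <- list(f1 = -Inf, params = model$params, epoch = -1L)
  stale <- 0L
  hist <- vector("list", tc$epochs)
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- lr_schedule(epoch, tc$epochs, tc$warmup, tc$lr_init, tc$lr_final)
    ord <- with_seed(derive_seed(tc$seed, 100L + epoch), sample.int(n))
    sums <- c(cls = 0, cm = 0, sparse = 0, total = 0)
    for (start in seq(1L, n, by = tc$batch_size)) {
      bi <- ord[start:min(start + tc$batch_size - 1L, n)]
      if (full_input$type == "vit") {
        rows <- as.vector(outer(seq_len(N), (bi - 1L) * N, "+"))
        binput <- list(type = "vit", B = length(bi),
                       Xp_flat = full_input$Xp_flat[rows, , drop = FALSE])
      } else {
        binput <- list(type = "conv", B = length(bi),
                       images = full_input$images[bi])
      }
      fwd <- cmf_forward(model, binput, prepared$train$labs[bi],
                         keep_cache = TRUE)
      bwd <- cmf_backward(model, fwd, prepared$train$labels[bi],
                          alpha = tc$alpha, beta = tc$beta)
      if (!is.finite(bwd$loss$total))
        stop_cmf(sprintf("training diverged at epoch %d (loss = %s)",
                         epoch, format(bwd$loss$total)))
      upd <- adamw_step(model$params, bwd$grads, opt, model$trainable, lr,
                        tc$beta1, tc$beta2, tc$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      w <- length(bi) / n
      sums <- sums + w * unlist(bwd$loss)
    }
    vfwd <- cmf_forward(model, val_input, prepared$val$labs)
    vpred <- max.col(vfwd$probs, "first") - 1L
    vcm <- confusion_matrix(vpred, prepared$val$labels, config$n_classes)
    vacc <- sum(diag(vcm)) / sum(vcm)
    vf1 <- f1_macro_from_confusion(vcm)
    hist[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, loss_total = sums["total"],
      loss_cls = sums["cls"], loss_cm = sums["cm"],
      loss_sparse = sums["sparse"], val_accuracy = vacc, val_f1 = vf1,
      row.names = NULL)
    if (tc$verbose)
      message(sprintf("epoch %3d lr %.2e loss %.4f val_acc %.3f val_f1 %.3f",
                      epoch, lr, sums["total"], vacc, vf1))
    if (vf1 > best$f1) {
      best <- list(f1 = vf1, params = model$params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= tc$patience) break
    }
  }
  model$params <- best$params
  structure(list(model = model,
                 history = do.call(rbind, hist[!vapply(hist, is.null,
                                                       logical(1))]),
                 best_epoch = best$epoch, best_val_f1 = best$f1,
                 config = config, train_config = tc),
            class = "cmf_fit")
}

safe_cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Evaluate a model on a prepared split
#'
#' Runs the forward pass over the whole split and aggregates the metric
#' suite: accuracy, macro F1, macro one-vs-rest AUC, Cohen's kappa, feature
#' sparsity of the gated feature (percent of exact zeros), mean cross-modal
#' cosine similarity, trainable parameter count, forward FLOPs, and the loss
#' components (sparsity on the hard mask). Argmax ties break toward the
#' lowest class index.
#'
#' @param model A `cmf_model` or a `cmf_fit` (its best model is used).
#' @param split One split of a [cmf_prepare()] object.
#' @param alpha,beta Loss weights used for the reported loss components.
#' @return List of class `cmf_report`.
#' @export
cmf_evaluate <- function(model, split, alpha = 0.1, beta = 0.05) {
  if (inherits(model, "cmf_fit")) model <- model$model
  if (is.null(split) || length(split$labels) == 0)
    stop_cmf("cannot evaluate an empty split")
  fwd <- cmf_forward(model, prepare_image_input(model, split$images),
                     split$labs)
  pred <- max.col(fwd$probs, "first") - 1L
  C <- model$config$n_classes
  cm <- confusion_matrix(pred, split$labels, C)
  auc <- if (length(unique(split$labels)) >= 2)
    auc_from_scores(fwd$probs, split$labels) else NA_real_
  cms <- vapply(seq_len(fwd$B), function(i)
    safe_cosine(fwd$F_I[i, ], fwd$F_L[i, ]), numeric(1))
  loss <- loss_total(fwd$probs, split$labels, fwd$F_I, fwd$F_L, fwd$mask,
                     alpha = alpha, beta = beta)
  structure(list(
    n = fwd$B,
    confusion = cm,
    accuracy = sum(diag(cm)) / sum(cm),
    f1_macro = f1_macro_from_confusion(cm),
    auc_macro = auc,
    kappa = kappa_from_confusion(cm),
    feature_sparsity_pct = feature_sparsity(fwd$F_prune),
    cross_modal_sim = mean(cms, na.rm = TRUE),
    n_params = count_parameters(model),
    flops = estimate_flops(model),
    loss = list(cls = loss$cls, cm = loss$cm, sparse = loss$sparse,
                total = loss$total)
  ), class = "cmf_report")
}

#' @export
print.cmf_report <- function(x, ...) {
  cat(sprintf(paste0(
    "cmf_report (n = %d)\n",
    "  accuracy  %.4f   f1_macro %.4f   auc_macro %.4f   kappa %.4f\n",
    "  sparsity  %.1f%%   cross-modal cos %.4f\n",
    "  params    %s (%.3f M)   flops %s (%.4f G)\n",
    "  loss      total %.4f = cls %.4f + a*cm %.4f + b*sparse %.4f\n"),
    x$n, x$accuracy, x$f1_macro, x$auc_macro, x$kappa,
    x$feature_sparsity_pct, x$cross_modal_sim,
    format(x$n_params, big.mark = ","), x$n_params / 1e6,
    format(x$flops, big.mark = ","), x$flops / 1e9,
    x$loss$total, x$loss$cls, x$loss$cm, x$loss$sparse))
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param report A `cmf_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = report$accuracy, f1_macro = report$f1_macro,
    auc_macro = report$auc_macro, kappa = report$kappa,
    feature_sparsity_pct = report$feature_sparsity_pct,
    cross_modal_sim = report$cross_modal_sim,
    n_params = report$n_params, flops = report$flops,
    loss = report$loss
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a fitted model checkpoint
#'
#' Single-file serialized weight map with its configuration and a content
#' hash of the flattened weights for integrity checking on reload.
#'
#' @param fit A `cmf_fit` or `cmf_model`.
#' @param path Checkpoint file path.
#' @return `path` invisibly; [load_checkpoint()] returns the `cmf_model`.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "cmf_fit")) fit$model else fit
  blob <- list(params = model$params, trainable = model$trainable,
               config = unclass(model$config),
               hash = sum(abs(unlist(model$params))))
  saveRDS(blob, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  blob <- readRDS(path)
  if (abs(sum(abs(unlist(blob$params))) - blob$hash) > 1e-6)
    stop_cmf("checkpoint hash mismatch: file corrupted")
  cf <- structure(blob$config, class = "cmf_config")
  m <- structure(list(params = blob$params, trainable = blob$trainable,
                      config = cf, conv_plan = NULL), class = "cmf_model")
  if (cf$image_encoder == "conv") {
    H <- cf$image_size[1]; W <- cf$image_size[2]
    chans <- c(cf$image_size[3], cf$conv_channels)
    m$conv_plan <- lapply(1:3, function(l) {
      pl <- conv_im2col_plan(H %/% 2^(l - 1L), W %/% 2^(l - 1L), chans[l])
      pl
    })
  }
  m
}
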