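## Experiment protocols: module ablation, pruning-coefficient sweep,
## perturbation robustness, repeated stratified cross-validation, and the
## gate-selectivity attribution used to inspect what SmartTrim retains.

#' Strong-signal synthetic preset
#'
#' The reference desk-scale study condition: 600 samples, 4 classes,
#' 32 x 32 x 3 images, T = 10 time steps, K = 8 laboratory dimensions of
#' which half are pure noise, motif amplitude 3 noise standard deviations,
#' cross-modal coupling 0.8.
#'
#' @param seed Dataset seed.
#' @param n_samples Number of samples (default 600).
#' @return A [synth_spec()].
#' @export
preset_strong_signal <- function(seed = 1L, n_samples = 600L) {
  synth_spec(n_samples = n_samples, n_classes = 4L,
             image_size = c(32L, 32L, 3L), T_steps = 10L, K = 8L,
             signal_strength = 3, cross_modal_coupling = 0.8,
             redundant_fraction = 0.5, seed = seed)
}

ablation_grid <- function() {
  data.frame(
    name = c("full", "-ViT", "-SmartTrim", "-CMT", "-ViT-SmartTrim",
             "-ViT-CMT", "-SmartTrim-CMT"),
    use_image_transformer = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    use_smarttrim = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    use_cmt = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
}

apply_toggles <- function(config, vit, smarttrim, cmt) {
  config$image_encoder <- if (vit) "vit" else "conv"
  config$smarttrim <- smarttrim
  config$fusion <- cmt
  config
}

#' Module ablation protocol
#'
#' Trains and evaluates the seven toggle combinations of the ablation
#' protocol (full model; each module removed alone; each pair removed) with
#' shared data splits and shared per-seed initialization/order seeds, so
#' rows differ only by architecture. Removing the image transformer
#' substitutes the 3-block convolutional encoder with matched output
#' dimension; removing SmartTrim passes `F_cat` through unchanged; removing
#' the fusion module feeds the gated concatenation through a linear 2d -> d
#' adapter into the head.
#'
#' @param dataset A `cmf_dataset`.
#' @param config Base [cmf_config()].
#' @param tc Base [train_config()].
#' @param seeds Integer vector of run seeds (default `1:3`).
#' @param split_seed Seed of the shared stratified split.
#' @return List with `table` (per-combination seed-mean metrics with the
#'   toggle triple) and `reports` (per-combination, per-seed `cmf_report`s).
#' @export
run_ablation <- function(dataset, config, tc = train_config(),
                         seeds = 1:3, split_seed = 1L) {
  prepared <- cmf_prepare(dataset, config, seed = split_seed)
  grid <- ablation_grid()
  reports <- list()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- apply_toggles(config, grid$use_image_transformer[i],
                         grid$use_smarttrim[i], grid$use_cmt[i])
    per_seed <- lapply(seeds, function(s) {
      tcs <- tc; tcs$seed <- as.integer(s)
      fit <- cmf_train(prepared, cfg, tcs)
      cmf_evaluate(fit, prepared$test, alpha = tc$alpha, beta = tc$beta)
    })
    reports[[grid$name[i]]] <- per_seed
    pick <- function(f) mean(vapply(per_seed, `[[`, numeric(1), f))
    rows[[i]] <- data.frame(
      grid[i, , drop = FALSE],
      accuracy = pick("accuracy"), f1_macro = pick("f1_macro"),
      auc_macro = pick("auc_macro"), kappa = pick("kappa"),
      feature_sparsity_pct = pick("feature_sparsity_pct"),
      cross_modal_sim = pick("cross_modal_sim"),
      n_params = per_seed[[1]]$n_params, flops = per_seed[[1]]$flops,
      row.names = NULL)
  }
  list(table = do.call(rbind, rows), reports = reports)
}

#' Pruning-coefficient sensitivity sweep
#'
#' Trains and evaluates the model at each threshold coefficient `lambda`
#' with shared splits and seeds, reporting accuracy, macro F1, feature
#' sparsity and parameter count per value.
#'
#' @param dataset A `cmf_dataset`.
#' @param config Base [cmf_config()].
#' @param tc Base [train_config()].
#' @param values Lambda values (default `c(0.1, 0.2, 0.3, 0.4, 0.5)`).
#' @param seeds Run seeds to average over.
#' @param split_seed Seed of the shared stratified split.
#' @return Data frame with one row per `lambda`.
#' @export
sweep_lambda <- function(dataset, config, tc = train_config(),
                         values = c(0.1, 0.2, 0.3, 0.4, 0.5), seeds = 1:3,
                         split_seed = 1L) {
  prepared <- cmf_prepare(dataset, config, seed = split_seed)
  rows <- lapply(values, function(lv) {
    cfg <- config
    cfg$lambda <- lv
    per_seed <- lapply(seeds, function(s) {
      tcs <- tc; tcs$seed <- as.integer(s)
      fit <- cmf_train(prepared, cfg, tcs)
      cmf_evaluate(fit, prepared$test, alpha = tc$alpha, beta = tc$beta)
    })
    pick <- function(f) mean(vapply(per_seed, `[[`, numeric(1), f))
    data.frame(lambda = lv, accuracy = pick("accuracy"),
               f1_macro = pick("f1_macro"),
               feature_sparsity_pct = pick("feature_sparsity_pct"),
               n_params = per_seed[[1]]$n_params)
  })
  do.call(rbind, rows)
}

#' Perturbation robustness protocol
#'
#' Evaluates a trained model on the test split under (a) Gaussian image
#' noise with variance growing linearly in the interference level and (b)
#' random masking of laboratory entries re-imputed with the training median,
#' at each level, averaging nonzero levels over `n_seeds` perturbation
#' seeds. Level 0 is the unperturbed evaluation, bit-exact.
#'
#' @param fit A `cmf_fit` (or `cmf_model`).
#' @param prepared The [cmf_prepare()] object the model was trained on (its
#'   `test` split and laboratory statistics are used).
#' @param levels Interference intensities (default `c(0, 0.1, 0.2, 0.3,
#'   0.4)`).
#' @param n_seeds Perturbation seeds per nonzero level (default 3).
#' @param seed Base seed the perturbation seeds are derived from.
#' @return Data frame with columns `perturbation`, `level`, `accuracy`,
#'   `accuracy_sd`.
#' @export
run_robustness <- function(fit, prepared, levels = c(0, 0.1, 0.2, 0.3, 0.4),
                           n_seeds = 3L, seed = 1L) {
  model <- if (inherits(fit, "cmf_fit")) fit$model else fit
  test <- prepared$test
  base_acc <- cmf_evaluate(model, test)$accuracy
  rows <- list()
  for (type in c("image_noise", "lab_missing")) {
    for (lv in levels) {
      if (lv == 0) {
        accs <- base_acc
      } else {
        accs <- vapply(seq_len(n_seeds), function(r) {
          ps <- derive_seed(seed, 900L + 10L * r + round(100 * lv))
          split2 <- test
          if (type == "image_noise") {
            split2$images <- with_seed(ps, lapply(test$images,
              function(im) perturb_image_noise(im, lv, v_max = 1)))
          } else {
            split2$labs <- with_seed(ps, lapply(test$labs,
              function(lb) perturb_lab_missing(lb, lv, prepared$stats,
                                               scaled = TRUE)))
          }
          cmf_evaluate(model, split2)$accuracy
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        perturbation = type, level = lv, accuracy = mean(accs),
        accuracy_sd = if (length(accs) > 1) stats::sd(accs) else 0)
    }
  }
  do.call(rbind, rows)
}

#' Repeated stratified k-fold cross-validation
#'
#' `n_repeats` independent stratified shuffles, each split into `k` folds;
#' every fold serves once as the test set while a stratified 15% of the
#' remaining samples is carved out as the early-stopping validation set and
#' the rest trains a freshly initialized model. Reports the per-metric mean
#' and standard deviation over all `k * n_repeats` fits.
#'
#' @param dataset A `cmf_dataset`.
#' @param config A [cmf_config()].
#' @param tc A [train_config()].
#' @param k Folds per repeat (every class must have at least `k` samples).
#' @param n_repeats Independent shuffles.
#' @param seed Base seed.
#' @return List with `summary` (metric, mean, sd) and `fits` (per-fold
#'   metric data frame).
#' @export
cross_validate <- function(dataset, config, tc = train_config(), k = 5L,
                           n_repeats = 3L, seed = 1L) {
  labels <- dataset_labels(dataset)
  if (min(table(labels)) < k)
    stop_cmf(sprintf("every class needs at least k = %d samples", k))
  rows <- list()
  for (r in seq_len(n_repeats)) {
    folds <- with_seed(derive_seed(seed, 300L + r), {
      f <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        f[idx] <- rep(seq_len(k), length.out = length(idx))
      }
      f
    })
    for (fold in seq_len(k)) {
      test_idx <- which(folds == fold)
      rest <- which(folds != fold)
      carve <- stratified_split(labels[rest], ratios = c(0.85, 0.15),
                               seed = derive_seed(seed, 400L + 7L * r + fold))
      split <- list(train = rest[carve[[1]]], val = rest[carve[[2]]],
                    test = test_idx)
      prepared <- cmf_prepare(dataset, config, split = split)
      tcs <- tc
      tcs$seed <- derive_seed(seed, 500L + 11L * r + fold)
      fit <- cmf_train(prepared, config, tcs)
      rep_ <- cmf_evaluate(fit, prepared$test, alpha = tc$alpha,
                           beta = tc$beta)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = fold, n_test = rep_$n,
        accuracy = rep_$accuracy, f1_macro = rep_$f1_macro,
        auc_macro = rep_$auc_macro, kappa = rep_$kappa,
        feature_sparsity_pct = rep_$feature_sparsity_pct,
        cross_modal_sim = rep_$cross_modal_sim)
    }
  }
  fits <- do.call(rbind, rows)
  mets <- c("accuracy", "f1_macro", "auc_macro", "kappa",
            "feature_sparsity_pct", "cross_modal_sim")
  list(summary = data.frame(
         metric = mets,
         mean = vapply(mets, function(m) mean(fits[[m]]), numeric(1)),
         sd = vapply(mets, function(m) stats::sd(fits[[m]]), numeric(1)),
         row.names = NULL),
       fits = fits)
}

#' Score-weighted sensitivity of the gate to each laboratory dimension
#'
#' The importance scores live on the 2d-dimensional embedding, not on the
#' raw K laboratory dimensions, so gate selectivity for raw dimensions is
#' measured by attribution: for raw dimension k, the mean over samples of
#' `sum_j S_{d+j} * |dF_L,j / dx_{t,k}|`, using the exact piecewise-linear
#' Jacobian of the laboratory MLP averaged over time steps. Trained on data
#' where some dimensions are pure noise, signal-carrying dimensions should
#' score higher.
#'
#' @param model A `cmf_model` or `cmf_fit`.
#' @param split A prepared split (images and labs are both needed, since the
#'   scores depend on the concatenated embedding).
#' @return Numeric vector of length K.
#' @export
lab_dim_importance <- function(model, split) {
  if (inherits(model, "cmf_fit")) model <- model$model
  if (!model$config$smarttrim)
    stop_cmf("gate attribution requires the SmartTrim module")
  p <- model$params
  d <- model$config$d
  fwd <- cmf_forward(model, prepare_image_input(model, split$images),
                     split$labs)
  K <- nrow(p$lab_W1)
  imp <- numeric(K)
  for (b in seq_len(fwd$B)) {
    L <- split$labs[[b]]
    pre1 <- linear_fwd(L, p$lab_W1, p$lab_b1)
    pre2 <- linear_fwd(relu(pre1), p$lab_W2, p$lab_b2)
    Tn <- nrow(L)
    A <- matrix(0, K, d)
    for (t in seq_len(Tn)) {
      J <- sweep(p$lab_W1, 2, pre1[t, ] > 0, "*") %*% p$lab_W2
      J <- sweep(J, 2, pre2[t, ] > 0, "*")
      A <- A + abs(J)
    }
    imp <- imp + drop((A / Tn) %*% fwd$S[b, d + seq_len(d)])
  }
  imp / fwd$B
}
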