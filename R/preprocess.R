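## Preprocessing and perturbation: image resize/standardize/augment,
## laboratory 3-sigma outlier handling + median imputation + min-max scaling
## + temporal interpolation, robustness perturbations, stratified splitting.

resize_channel <- function(m, th, tw) {
  if (nrow(m) == th && ncol(m) == tw) return(m)
  ## EBImage indexes (x, y) = (dim1, dim2); passing the H x W matrix directly
  ## with w = target H keeps our row/column convention intact.
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = th, h = tw,
                                            filter = "bilinear"))
  matrix(out, th, tw)
}

#' Preprocess an image: resize, optional augmentation, z-score standardize
#'
#' Pipeline: (train mode only) random horizontal flip with probability 0.5,
#' random crop with area ratio drawn uniformly in `[0.8, 1]` then bilinear
#' resize back, Gaussian blur with standard deviation drawn uniformly in
#' `[0, blur_max]`; then bilinear resize to `target_size`; then per-image,
#' per-channel z-score standardization (mean 0, population variance 1). A
#' zero-variance channel standardizes to all zeros rather than erroring.
#'
#' Augmentation draws come from the current RNG stream unless `seed` is
#' given, in which case the draws are taken under that seed and the caller's
#' stream is left untouched.
#'
#' @param image H x W x channels array (a plain matrix is treated as one
#'   channel).
#' @param target_size Integer `c(H, W)` of the output (default `c(224, 224)`;
#'   toy sizes are fine).
#' @param train_mode Apply the random augmentations?
#' @param blur_max Upper bound of the blur standard deviation in pixels
#'   (default 0.1).
#' @param seed Optional integer seed for the augmentation draws.
#' @return `target_size[1]` x `target_size[2]` x channels array with
#'   per-channel mean 0 and population variance 1 (or a constant-0 channel).
#' @export
preprocess_image <- function(image, target_size = c(224L, 224L),
                             train_mode = FALSE, blur_max = 0.1,
                             seed = NULL) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  if (length(d) != 3L || d[1] < 1 || d[2] < 1)
    stop_cmf("'image' must have positive spatial extent (H x W x channels)")
  run <- function() {
    H <- d[1]; W <- d[2]; CH <- d[3]
    out <- image
    if (train_mode) {
      if (stats::runif(1) < 0.5) out <- out[, rev(seq_len(W)), , drop = FALSE]
      ratio <- stats::runif(1, 0.8, 1)
      chh <- max(1L, round(H * sqrt(ratio)))
      cww <- max(1L, round(W * sqrt(ratio)))
      oy <- if (chh < H) sample.int(H - chh + 1L, 1L) else 1L
      ox <- if (cww < W) sample.int(W - cww + 1L, 1L) else 1L
      crop <- out[oy:(oy + chh - 1L), ox:(ox + cww - 1L), , drop = FALSE]
      out <- array(0, dim = c(H, W, CH))
      for (ch in seq_len(CH)) out[, , ch] <- resize_channel(crop[, , ch], H, W)
      bsd <- stats::runif(1, 0, blur_max)
      if (bsd > 0) {
        for (ch in seq_len(CH)) {
          b <- EBImage::imageData(EBImage::gblur(EBImage::Image(out[, , ch]),
                                                 sigma = bsd))
          out[, , ch] <- matrix(b, H, W)
        }
      }
    }
    th <- target_size[1]; tw <- target_size[2]
    if (th != H || tw != W) {
      res <- array(0, dim = c(th, tw, CH))
      for (ch in seq_len(CH)) res[, , ch] <- resize_channel(out[, , ch], th, tw)
      out <- res
    }
    for (ch in seq_len(dim(out)[3])) {
      v <- out[, , ch]
      s <- pop_sd(v)
      out[, , ch] <- if (s == 0) 0 else (v - mean(v)) / s
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Compute frozen laboratory preprocessing statistics from a training split
#'
#' Per feature: `mean` and `sd` of the raw (non-missing) training values used
#' for the 3-sigma outlier rule; `median` of the training values that survive
#' that rule (the imputation value); `min`/`max` of the outlier-masked,
#' median-imputed training values (the min--max scaling anchors); and
#' `median_scaled`, the imputation value mapped into `[0, 1]`.
#'
#' @param lab_list List of T x K matrices (the training split's series).
#' @return List of per-feature vectors, class `cmf_lab_stats`.
#' @export
lab_stats <- function(lab_list) {
  all <- do.call(rbind, lab_list)
  K <- ncol(all)
  mu <- sdv <- med <- lo <- hi <- numeric(K)
  for (k in seq_len(K)) {
    v <- all[, k]
    mu[k] <- mean(v, na.rm = TRUE)
    sdv[k] <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(sdv[k])) sdv[k] <- 0
    keep <- !is.na(v) & abs(v - mu[k]) <= 3 * sdv[k]
    med[k] <- stats::median(v[keep])
    w <- v
    w[!keep | is.na(w)] <- med[k]
    lo[k] <- min(w)
    hi[k] <- max(w)
  }
  span <- hi - lo
  med_scaled <- ifelse(span > 0, (med - lo) / span, 0.5)
  structure(list(mean = mu, sd = sdv, median = med, min = lo, max = hi,
                 median_scaled = med_scaled), class = "cmf_lab_stats")
}

#' Preprocess one laboratory series with frozen training statistics
#'
#' Pipeline order: (1) values outside `mean +/- 3*sd` (training statistics)
#' are marked missing; (2) missing values are imputed with the per-feature
#' training median; (3) min--max scaling to `[0, 1]` with training min/max,
#' clipped to `[0, 1]` (a constant training feature maps to 0.5); (4) linear
#' interpolation along time to `T_target` points.
#'
#' @param series T x K numeric matrix, possibly containing `NA`.
#' @param stats A [lab_stats()] object.
#' @param T_target Output length along time (default: keep `nrow(series)`).
#' @return `T_target` x K matrix with values in `[0, 1]` and no `NA`.
#' @export
preprocess_lab <- function(series, stats, T_target = NULL) {
  series <- as.matrix(series)
  if (nrow(series) < 2) stop_cmf("'series' needs at least 2 time points")
  if (!inherits(stats, "cmf_lab_stats")) stop_cmf("'stats' must come from lab_stats()")
  K <- ncol(series)
  if (length(stats$mean) != K) stop_cmf("feature count mismatch with stats")
  if (is.null(T_target)) T_target <- nrow(series)
  out <- matrix(0, T_target, K)
  for (k in seq_len(K)) {
    v <- series[, k]
    v[!is.na(v) & abs(v - stats$mean[k]) > 3 * stats$sd[k]] <- NA
    v[is.na(v)] <- stats$median[k]
    span <- stats$max[k] - stats$min[k]
    v <- if (span > 0) pmin(pmax((v - stats$min[k]) / span, 0), 1)
         else rep(0.5, length(v))
    out[, k] <- if (T_target == length(v)) v else {
      stats::approx(seq_along(v), v,
                    xout = seq(1, length(v), length.out = T_target))$y
    }
  }
  out
}

#' Add Gaussian noise to a standardized image
#'
#' Noise is mean 0 with variance `intensity * v_max`, i.e. variance grows
#' linearly with the interference intensity. `intensity = 0` returns the
#' input bit-identically (no RNG draw).
#'
#' @param image Numeric array (already standardized).
#' @param intensity Interference intensity in `[0, 1]`.
#' @param v_max Variance at intensity 1 (default 1).
#' @param seed Optional seed for the noise draw.
#' @return Perturbed array of the same shape.
#' @export
perturb_image_noise <- function(image, intensity, v_max = 1, seed = NULL) {
  check_number(intensity, "intensity", 0, 1)
  if (intensity == 0) return(image)
  draw <- function() image +
    array(stats::rnorm(length(image), sd = sqrt(intensity * v_max)),
          dim = dim(image) %||% length(image))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomly mask laboratory entries and re-impute with the training median
#'
#' Exactly `round(fraction * T * K)` entries chosen uniformly without
#' replacement are set missing and then replaced by the per-feature training
#' median (the same imputation step the preprocessing pipeline uses). For a
#' series already scaled to `[0, 1]` use `scaled = TRUE` (the default), which
#' imputes with the scaled median.
#'
#' @param series T x K matrix.
#' @param fraction Fraction of entries to mask, in `[0, 1]`.
#' @param stats A [lab_stats()] object.
#' @param scaled Is `series` on the min--max-scaled scale?
#' @param seed Optional seed for the mask draw.
#' @return Matrix with the masked entries imputed.
#' @export
perturb_lab_missing <- function(series, fraction, stats, scaled = TRUE,
                                seed = NULL) {
  check_number(fraction, "fraction", 0, 1)
  n <- length(series)
  n_mask <- round(fraction * n)
  if (n_mask == 0) return(series)
  imp <- if (scaled) stats$median_scaled else stats$median
  draw <- function() {
    idx <- sample.int(n, n_mask)
    cols <- (idx - 1L) %/% nrow(series) + 1L
    series[idx] <- imp[cols]
    series
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Stratified train/validation/test split
#'
#' Per class, sample order is shuffled and counts are allocated by largest
#' remainder; remainder ties are broken by a per-class rotating preference
#' over the splits so rounding surplus spreads across splits instead of
#' accumulating in the first one. Deterministic given `seed`.
#'
#' @param labels Integer label vector (or a `cmf_dataset`).
#' @param ratios Split proportions summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @param seed Integer seed.
#' @return List of index vectors `train`, `val`, `test` (1-based, disjoint,
#'   covering all samples).
#' @export
stratified_split <- function(labels, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (inherits(labels, "cmf_dataset")) labels <- dataset_labels(labels)
  if (abs(sum(ratios) - 1) > 1e-9) stop_cmf("'ratios' must sum to 1")
  if (any(ratios < 0)) stop_cmf("'ratios' must be nonnegative")
  ns <- length(ratios)
  parts <- rep(list(integer(0)), ns)
  classes <- sort(unique(labels))
  with_seed(seed, {
    for (j in seq_along(classes)) {
      idx <- which(labels == classes[j])
      idx <- idx[sample.int(length(idx))]
      exact <- length(idx) * ratios
      base <- floor(exact)
      frac <- exact - base
      rem <- length(idx) - sum(base)
      if (rem > 0) {
        pref <- ((seq_len(ns) - 1 + (j - 1)) %% ns) + 1  # rotating tie-break
        ord <- order(-frac, order(pref))
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
      }
      stops <- cumsum(base)
      starts <- c(1, utils::head(stops, -1) + 1)
      for (s in seq_len(ns)) {
        if (base[s] > 0)
          parts[[s]] <- c(parts[[s]], idx[starts[s]:stops[s]])
      }
    }
  })
  names(parts) <- if (ns == 3) c("train", "val", "test") else
    paste0("split", seq_len(ns))
  lapply(parts, sort)
}
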