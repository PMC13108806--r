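## Synthetic paired image + laboratory time-series generator.
##
## Emulates the structure of paired radiology / dermoscopy images with
## laboratory panels of K time-resolved indicators: each class carries a
## distinct spatial image motif and a distinct temporal laboratory profile,
## a per-sample latent couples the two modalities, and a configurable
## fraction of laboratory dimensions is pure noise (redundant).

#' Specification for a synthetic paired dataset
#'
#' @param n_samples Number of samples to generate.
#' @param n_classes Number of classes `C`; labels are integers in `[0, C)`.
#' @param image_size Integer vector `c(H, W, channels)` in pixels. `H` and `W`
#'   must be divisible by `patch` so the downstream patch tokenizer accepts
#'   the images unchanged.
#' @param T_steps Time steps per laboratory series (clinical panels are
#'   typically 8--12 repeated draws).
#' @param K Laboratory feature count per time step (typically 8--15
#'   indicators).
#' @param signal_strength Motif amplitude expressed in units of the
#'   pixel/feature noise standard deviation (which is 1). 0 plants no class
#'   signal at all.
#' @param cross_modal_coupling Weight in `[0, 1]` of a shared per-sample
#'   latent injected into both modalities; drives genuine cross-modal
#'   correlation beyond the class label.
#' @param redundant_fraction Fraction in `[0, 1)` of laboratory dimensions
#'   that carry pure noise (no class signal, no latent).
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   dataset.
#' @param patch Patch size the images must be compatible with (default 16).
#' @param missing_rate Fraction of laboratory entries set missing (`NA`), to
#'   exercise the median-imputation path (default 0.02).
#' @return An object of class `cmf_spec`.
#' @export
synth_spec <- function(n_samples, n_classes, image_size = c(32L, 32L, 3L),
                       T_steps = 10L, K = 8L, signal_strength = 3,
                       cross_modal_coupling = 0.8, redundant_fraction = 0.5,
                       seed = 1L, patch = 16L, missing_rate = 0.02) {
  check_number(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_number(n_classes, "n_classes", lower = 1, integer = TRUE)
  if (length(image_size) != 3L || any(image_size < 1))
    stop_cmf("'image_size' must be c(H, W, channels) with positive entries")
  check_number(T_steps, "T_steps", lower = 2, integer = TRUE)
  check_number(K, "K", lower = 1, integer = TRUE)
  check_number(signal_strength, "signal_strength", lower = 0)
  check_number(cross_modal_coupling, "cross_modal_coupling", 0, 1)
  check_number(redundant_fraction, "redundant_fraction", 0, 1,
               strict_upper = TRUE)
  check_number(missing_rate, "missing_rate", 0, 1)
  if (image_size[1] %% patch != 0 || image_size[2] %% patch != 0)
    stop_cmf(sprintf("image H and W must be divisible by the patch size %d",
                     patch))
  structure(list(
    n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
    image_size = as.integer(image_size), T_steps = as.integer(T_steps),
    K = as.integer(K), signal_strength = signal_strength,
    cross_modal_coupling = cross_modal_coupling,
    redundant_fraction = redundant_fraction, seed = as.integer(seed),
    patch = as.integer(patch), missing_rate = missing_rate
  ), class = "cmf_spec")
}

#' Generate a synthetic paired multimodal dataset
#'
#' Each sample is an image (class motif: a Gaussian bump at a class-specific
#' location, amplitude `signal_strength`, over unit pixel noise) paired with
#' a laboratory time-series matrix (class-specific sinusoid-plus-offset
#' temporal template on the signal-carrying dimensions over unit noise). A
#' per-sample latent `z ~ N(0,1)` is added to both modalities with weight
#' `cross_modal_coupling`: to the image as a smooth horizontal gradient, to
#' the signal-carrying laboratory dimensions as a constant shift. Exactly
#' `round(redundant_fraction * K)` laboratory dimensions receive pure noise.
#'
#' @param spec A [synth_spec()] object.
#' @return An object of class `cmf_dataset`: a list with `samples` (each a
#'   list of `sample_id`, `image` (H x W x channels array), `lab` (T x K
#'   matrix, possibly with `NA`), `label` in `[0, C)`), and attributes
#'   `signal_dims` / `noise_dims` recording which laboratory dimensions carry
#'   class signal.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "cmf_spec")) stop_cmf("'spec' must come from synth_spec()")
  H <- spec$image_size[1]; W <- spec$image_size[2]; CH <- spec$image_size[3]
  C <- spec$n_classes; Tn <- spec$T_steps; K <- spec$K
  n_noise <- as.integer(round(spec$redundant_fraction * K))
  with_seed(spec$seed, {
    noise_dims <- if (n_noise > 0) sort(sample.int(K, n_noise)) else integer(0)
    signal_dims <- setdiff(seq_len(K), noise_dims)

    ## Class-specific image motifs: Gaussian bump centred on a ring.
    ang <- 2 * pi * (seq_len(C) - 1) / max(C, 1)
    cy <- H / 2 + (H / 4) * sin(ang)
    cx <- W / 2 + (W / 4) * cos(ang)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    bump_sd <- max(H, W) / 8
    motifs <- lapply(seq_len(C), function(c) {
      exp(-((rr - cy[c])^2 + (cc - cx[c])^2) / (2 * bump_sd^2))
    })
    ## Smooth coupling pattern shared by all samples (horizontal gradient).
    grad_pat <- (cc - (W + 1) / 2) / W

    ## Class-specific laboratory temporal templates on signal dims.
    tgrid <- 2 * pi * (seq_len(Tn) - 1) / Tn
    amp <- matrix(stats::rnorm(C * K), C, K)
    off <- matrix(stats::rnorm(C * K), C, K)
    phase <- matrix(stats::runif(C * K, 0, 2 * pi), C, K)

    labels <- sample(rep(seq_len(C) - 1L, length.out = spec$n_samples))
    samples <- vector("list", spec$n_samples)
    for (i in seq_len(spec$n_samples)) {
      cl <- labels[i] + 1L
      z <- stats::rnorm(1)
      img <- array(stats::rnorm(H * W * CH), dim = c(H, W, CH))
      for (ch in seq_len(CH)) {
        img[, , ch] <- img[, , ch] +
          spec$signal_strength * motifs[[cl]] +
          spec$cross_modal_coupling * z * grad_pat
      }
      lab <- matrix(stats::rnorm(Tn * K), Tn, K)
      for (k in signal_dims) {
        lab[, k] <- lab[, k] + spec$signal_strength *
          (amp[cl, k] * sin(tgrid + phase[cl, k]) + off[cl, k]) +
          spec$cross_modal_coupling * z
      }
      if (spec$missing_rate > 0) {
        nmiss <- round(spec$missing_rate * Tn * K)
        if (nmiss > 0) lab[sample.int(Tn * K, nmiss)] <- NA_real_
      }
      samples[[i]] <- list(sample_id = sprintf("s%05d", i), image = img,
                           lab = lab, label = labels[i])
    }
    structure(list(samples = samples, spec = spec),
              signal_dims = signal_dims, noise_dims = noise_dims,
              class = "cmf_dataset")
  })
}

#' @export
print.cmf_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "cmf_dataset: %d samples, %d classes, images %dx%dx%d, lab %dx%d (%d redundant dims)\n",
    s$n_samples, s$n_classes, s$image_size[1], s$image_size[2], s$image_size[3],
    s$T_steps, s$K, length(attr(x, "noise_dims"))))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset$samples, `[[`, integer(1), "label")
}

#' Write a dataset to the on-disk layout
#'
#' Writes `images/<sample_id>.png` (8-bit PNG behind a per-dataset affine
#' min--max transform recorded in `dataset_meta.json`), `labs.csv` with
#' columns `sample_id,time_index,f1..fK`, and `labels.csv` with
#' `sample_id,label`. The PNG quantization makes the image round-trip
#' approximate (within one 8-bit step of the affine transform); downstream
#' per-image standardization is invariant to the affine part.
#'
#' @param dataset A `cmf_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  imgs <- lapply(dataset$samples, `[[`, "image")
  lo <- min(vapply(imgs, min, numeric(1)))
  hi <- max(vapply(imgs, max, numeric(1)))
  if (hi <= lo) hi <- lo + 1
  for (s in dataset$samples) {
    png::writePNG((s$image - lo) / (hi - lo),
                  file.path(dir, "images", paste0(s$sample_id, ".png")))
  }
  K <- ncol(dataset$samples[[1]]$lab)
  labs <- do.call(rbind, lapply(dataset$samples, function(s) {
    data.frame(sample_id = s$sample_id, time_index = seq_len(nrow(s$lab)),
               s$lab)
  }))
  names(labs)[-(1:2)] <- paste0("f", seq_len(K))
  utils::write.csv(labs, file.path(dir, "labs.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sample_id = vapply(dataset$samples, `[[`, character(1),
                                  "sample_id"),
               label = dataset_labels(dataset)),
    file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- list(pixel_min = lo, pixel_max = hi, spec = unclass(dataset$spec),
               signal_dims = attr(dataset, "signal_dims"),
               noise_dims = attr(dataset, "noise_dims"))
  jsonlite::write_json(meta, file.path(dir, "dataset_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset from the on-disk layout
#'
#' @param dir Directory written by [write_dataset()] (or hand-assembled in
#'   the same layout; `dataset_meta.json` is optional, in which case pixel
#'   values are taken as stored).
#' @return A `cmf_dataset`.
#' @export
read_dataset <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            colClasses = c(sample_id = "character"))
  labs <- utils::read.csv(file.path(dir, "labs.csv"),
                          colClasses = c(sample_id = "character"))
  meta_path <- file.path(dir, "dataset_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  fcols <- grep("^f\\d+$", names(labs), value = TRUE)
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    sid <- labels$sample_id[i]
    img <- png::readPNG(file.path(dir, "images", paste0(sid, ".png")))
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (!is.null(meta)) {
      img <- img * (meta$pixel_max - meta$pixel_min) + meta$pixel_min
    }
    block <- labs[labs$sample_id == sid, , drop = FALSE]
    block <- block[order(block$time_index), , drop = FALSE]
    list(sample_id = sid, image = img,
         lab = as.matrix(block[, fcols, drop = FALSE]),
         label = as.integer(labels$label[i]))
  })
  spec <- if (!is.null(meta)) {
    structure(lapply(meta$spec, function(v)
      if (is.list(v)) unlist(v) else v), class = "cmf_spec")
  } else NULL
  structure(list(samples = samples, spec = spec),
            signal_dims = if (!is.null(meta)) unlist(meta$signal_dims),
            noise_dims = if (!is.null(meta)) unlist(meta$noise_dims),
            class = "cmf_dataset")
}
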