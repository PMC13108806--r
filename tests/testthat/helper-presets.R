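# Small shared fixtures, built in code.

tiny_config <- function(...) {
  cmf_config(d = 16L, heads = 2L, depth = 1L, n_classes = 3L,
             image_size = c(16L, 16L, 2L), patch = 8L, T_steps = 4L, K = 5L,
             ...)
}

tiny_dataset <- function(n = 45L, seed = 9L, ...) {
  generate_dataset(synth_spec(
    n_samples = n, n_classes = 3L, image_size = c(16L, 16L, 2L),
    T_steps = 4L, K = 5L, redundant_fraction = 0.4, seed = seed,
    patch = 8L, ...))
}

random_image <- function(H = 16L, W = 16L, CH = 2L) {
  array(rnorm(H * W * CH), dim = c(H, W, CH))
}

random_labs <- function(B, T_steps = 4L, K = 5L) {
  lapply(seq_len(B), function(i) matrix(runif(T_steps * K), T_steps, K))
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
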