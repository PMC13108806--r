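## Internal utilities: seed handling, validation, small numeric helpers.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations are pure functions of their
#' inputs and do not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a run seed; result stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647L)
}

stop_cmf <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE,
                         strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_cmf(sprintf("'%s' must be a single finite number", name))
  if (integer && x != round(x))
    stop_cmf(sprintf("'%s' must be an integer", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_cmf(sprintf("'%s' = %s is outside the valid range %s%s, %s%s",
                     name, format(x),
                     if (strict_lower) "(" else "[", format(lower),
                     format(upper), if (strict_upper) ")" else "]"))
  invisible(x)
}

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax for a matrix of logits.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-major tiling helper: repeats the rows of `m` (S x d) B times,
# giving a (B*S) x d matrix whose row blocks all equal `m`.
tile_rows <- function(m, B) m[rep(seq_len(nrow(m)), times = B), , drop = FALSE]
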