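#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive `n` child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_dyadkin <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Smooth standard Gaussian noise: white noise convolved with a Gaussian
# kernel (SD `smooth` frames), rescaled to unit variance.
smooth_noise <- function(n, smooth = 12) {
  half <- ceiling(3 * smooth)
  k <- stats::dnorm(seq(-half, half), sd = smooth)
  k <- k / sum(k)
  x <- stats::rnorm(n + 2L * half)
  y <- stats::filter(x, k, sides = 2)
  y <- y[(half + 1L):(half + n)]
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) return(rep(0, n))
  (y - mean(y)) / s
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
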