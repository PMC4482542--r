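#' Derive reproducible child seeds from a master seed
#'
#' All stochastic entry points in decaylab accept a single integer `seed` and
#' derive per-unit (per-subject, per-simulation, per-grid-point) child seeds
#' from it with this helper. Child seeds are drawn sequentially from a
#' Mersenne-Twister stream seeded at `seed`, so the first `k` children are
#' identical whatever the total number requested: enlarging a cohort does not
#' reshuffle earlier subjects.
#'
#' @param seed Integer master seed, or `NULL` to draw one from the current
#'   global RNG state.
#' @param n Number of child seeds to derive.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  sample.int(2147483646L, n, replace = TRUE)
}

#' Resolve a possibly-NULL seed to a concrete integer
#' @keywords internal
resolve_seed <- function(seed) {
  if (is.null(seed)) derive_seeds(NULL, 1L) else as.integer(seed)
}

# Run fn under a temporary RNG state seeded at `seed`, restoring the caller's
# state afterwards so package functions do not clobber user RNG flow.
with_seed <- function(seed, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  fn()
}

# Trapezoidal integral on a uniform grid with spacing dt.
trapz_uniform <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(0)
  dt * (sum(x) - (x[1L] + x[n]) / 2)
}

# Moving averages over full (valid) windows only: a length-n input yields
# n - w + 1 values; edges are not padded.
moving_average <- function(x, w) {
  n <- length(x)
  if (n < w) stop("series shorter than the smoothing window")
  cs <- cumsum(c(0, x))
  (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}
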