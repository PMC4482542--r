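#' Delayed exponential decay parameters
#'
#' Parameter set for the delayed exponential model of adaptation decay:
#' adaptation holds at a pre-decay asymptote `a` through trial `lam` (the
#' decay onset delay, counted relative to retention onset, where trial 1 is
#' the first retention trial), then relaxes exponentially with time constant
#' `tau` toward the retention asymptote `b`.
#'
#' @param a Pre-decay asymptotic adaptation (dimensionless adaptation units).
#' @param b Retention asymptote (adaptation units).
#' @param tau Decay time constant in trials; must be > 0.
#' @param lam Decay onset delay in trials relative to retention onset.
#' @return An object of class `delayed_exp_params`.
#' @examples
#' p <- delayed_exp_params(a = 0.85, b = 0.40, tau = 40, lam = 0)
#' eval_delayed_exponential(p, c(0, 40, 1000))
#' @export
delayed_exp_params <- function(a, b, tau, lam) {
  stopifnot_scalar(a, "a"); stopifnot_scalar(b, "b")
  stopifnot_scalar(tau, "tau"); stopifnot_scalar(lam, "lam")
  if (tau <= 0) stop("invalid parameter: `tau` must be > 0")
  structure(list(a = a, b = b, tau = tau, lam = lam),
            class = "delayed_exp_params")
}

#' @export
print.delayed_exp_params <- function(x, ...) {
  cat(sprintf(
    "Delayed exponential: a = %.4g, b = %.4g, tau = %.4g trials, lam = %.4g trials\n",
    x$a, x$b, x$tau, x$lam))
  invisible(x)
}

#' Evaluate the delayed exponential decay model
#'
#' Returns `a` for trials at or before the onset delay, and
#' `(a - b) * exp(-(t - lam) / tau) + b` afterwards. The function is
#' continuous at `t = lam`, where both branches equal `a`.
#'
#' @param p A [delayed_exp_params()] object.
#' @param t Trial index (vectorized), relative to retention onset: `t <= 0`
#'   is training, `t >= 1` retention.
#' @return Adaptation value(s), same length as `t`.
#' @export
eval_delayed_exponential <- function(p, t) {
  if (!inherits(p, "delayed_exp_params")) p <- do.call(delayed_exp_params, as.list(p)[c("a", "b", "tau", "lam")])
  ifelse(t <= p$lam, p$a, (p$a - p$b) * exp(-(t - p$lam) / p$tau) + p$b)
}

# Fast non-validating evaluator used in inner simulation/fitting loops.
dexp_eval <- function(a, b, tau, lam, t) {
  out <- rep.int(a, length(t))
  post <- t > lam
  if (any(post)) out[post] <- (a - b) * exp(-(t[post] - lam) / tau) + b
  out
}
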