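#' Population specification for simulated cohorts
#'
#' Distributions of per-subject delayed-exponential parameters and
#' measurement noise used by [simulate_cohort()]. Defaults are the
#' reference values for the group-level decay-onset analysis: pre-decay
#' asymptote a ~ N(0.875, 0.100^2), retention asymptote b ~ N(0.360,
#' 0.200^2), decay time constant tau ~ N(40, 10^2) trials, and independent
#' white trial noise with standard deviation 0.25 (adaptation units) — a
#' deliberate overestimate of behavioral noise that broadens simulated
#' likelihoods, making downstream inference conservative. Decay onset
#' delays are exponentially distributed across subjects with mean
#' `mu_lambda` trials; `mu_lambda = 0` denotes a point mass at zero
#' (immediate decay for every subject).
#'
#' @param a_mean,a_sd Mean and sd of the pre-decay asymptote.
#' @param b_mean,b_sd Mean and sd of the retention asymptote.
#' @param tau_mean,tau_sd Mean and sd of the decay time constant (trials).
#' @param noise_sd White measurement noise sd (adaptation units).
#' @param mu_lambda Mean of the exponential delay distribution (trials, >= 0).
#' @param n_subjects Subjects per cohort.
#' @param n_training,n_retention Trials in the training and retention blocks.
#' @param probe_frac Fraction of trials in each block replaced by zero-error
#'   clamp probes. Adaptation can only be measured on error-clamp trials, so
#'   during force-field training only this random subset of trials is
#'   observable; every retention trial is an error clamp and hence measured.
#'   Training-window statistics downstream honor this by averaging over
#'   probe trials only.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(a_mean = 0.875, a_sd = 0.100,
                            b_mean = 0.360, b_sd = 0.200,
                            tau_mean = 40, tau_sd = 10,
                            noise_sd = 0.25,
                            mu_lambda = 0,
                            n_subjects = 40L,
                            n_training = 300L,
                            n_retention = 325L,
                            probe_frac = 0.2) {
  for (nm in c("a_sd", "b_sd", "tau_sd", "noise_sd"))
    if (get(nm) < 0) stop(sprintf("`%s` must be >= 0", nm))
  if (mu_lambda < 0) stop("`mu_lambda` must be >= 0")
  if (probe_frac < 0 || probe_frac > 1) stop("`probe_frac` must be in [0, 1]")
  if (n_training < 1L || n_retention < 1L)
    stop("block lengths must be positive")
  structure(list(a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
                 tau_mean = tau_mean, tau_sd = tau_sd, noise_sd = noise_sd,
                 mu_lambda = mu_lambda, n_subjects = as.integer(n_subjects),
                 n_training = as.integer(n_training),
                 n_retention = as.integer(n_retention),
                 probe_frac = probe_frac),
            class = "population_spec")
}

#' Draw one subject's decay parameters from a population
#'
#' `a`, `b` and `tau` are drawn from the population normals (`tau` is
#' redrawn until positive, a vanishingly rare event at the default spread);
#' the onset delay is drawn from an exponential with mean `mu_lambda`,
#' defined as exactly 0 when `mu_lambda = 0`.
#'
#' Draws consume the current global RNG stream; seed the stream (or use
#' [simulate_cohort()], which derives per-subject child seeds) for
#' reproducibility.
#'
#' @param pop A [population_spec()].
#' @return A [delayed_exp_params()] object.
#' @export
draw_subject <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  a <- stats::rnorm(1L, pop$a_mean, pop$a_sd)
  b <- stats::rnorm(1L, pop$b_mean, pop$b_sd)
  tau <- stats::rnorm(1L, pop$tau_mean, pop$tau_sd)
  while (tau <= 0) tau <- stats::rnorm(1L, pop$tau_mean, pop$tau_sd)
  lam <- if (pop$mu_lambda == 0) 0 else stats::rexp(1L, rate = 1 / pop$mu_lambda)
  delayed_exp_params(a, b, tau, lam)
}
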