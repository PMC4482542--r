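#' Trial index vector for a training + retention session
#'
#' Trial `t = 0` is the last training trial and `t = 1` the first retention
#' trial; all analysis windows in the package use this convention, inclusive
#' on both ends.
#'
#' @param n_training,n_retention Block lengths in trials.
#' @return Integer vector `-(n_training - 1), ..., 0, 1, ..., n_retention`.
#' @export
trial_index <- function(n_training, n_retention) {
  seq.int(-(as.integer(n_training) - 1L), as.integer(n_retention))
}

#' Simulate one subject's adaptation trace
#'
#' The latent trace follows the delayed exponential in `p`; training-phase
#' noise is always white `N(0, noise_sd^2)`, while retention-phase noise is
#' white when `drift` is `NULL` and ARMA(1,1) otherwise. ARMA noise is
#' initialized at zero state at retention onset (`n(0) = 0`, `eps(0) = 0`,
#' no burn-in by default) so noise is continuous in expectation across the
#' abrupt phase change.
#'
#' @param p A [delayed_exp_params()] object.
#' @param noise_sd White-noise standard deviation for training (and for
#'   retention when `drift` is `NULL`).
#' @param drift Optional [arma_spec()] for correlated retention noise.
#' @param n_training,n_retention Block lengths in trials.
#' @param subject_id Identifier stored in the output.
#' @param seed Optional integer seed (a `NULL` seed draws from the global
#'   RNG stream).
#' @return A `trial_series` data frame with columns `subject_id`, `t`,
#'   `phase`, `probe`, `value`, and the generating parameters in
#'   `attr(, "truth")`.
#' @export
simulate_subject <- function(p, noise_sd, drift = NULL,
                             n_training = 300L, n_retention = 325L,
                             subject_id = "s1", seed = NULL) {
  stopifnot(inherits(p, "delayed_exp_params"))
  if (n_training < 1L || n_retention < 1L) stop("block lengths must be positive")
  seed <- resolve_seed(seed)
  t <- trial_index(n_training, n_retention)
  value <- with_seed(seed, function() {
    y <- dexp_eval(p$a, p$b, p$tau, p$lam, t)
    train_noise <- stats::rnorm(n_training, 0, noise_sd)
    ret_noise <- if (is.null(drift)) {
      stats::rnorm(n_retention, 0, noise_sd)
    } else {
      arma_recursion(drift$ar, drift$ma,
                     stats::rnorm(n_retention, 0, drift$eps_sd))
    }
    y + c(train_noise, ret_noise)
  })
  new_trial_series(subject_id, t, value, truth = p)
}

new_trial_series <- function(subject_id, t, value, probe = NA_character_,
                             truth = NULL) {
  out <- data.frame(subject_id = subject_id, t = as.integer(t),
                    phase = ifelse(t <= 0L, "training", "retention"),
                    probe = probe, value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_series", "data.frame")
  attr(out, "truth") <- truth
  out
}

#' Simulate a cohort of subjects
#'
#' Draws `pop$n_subjects` independent subjects from the population and
#' simulates each with [draw_subject()]-distributed parameters. Each subject
#' gets a deterministic child seed derived from `seed`, so the same seed
#' reproduces the cohort bit-for-bit and growing the cohort leaves earlier
#' subjects unchanged. The latent generating parameters are retained for
#' parameter-recovery analyses.
#'
#' @param pop A [population_spec()].
#' @param drift Optional [arma_spec()] applied to every subject's retention
#'   noise (the training noise stays white at `pop$noise_sd`).
#' @param seed Integer master seed.
#' @return A `decay_cohort`: list with `values` (n_subjects x n_trials
#'   matrix), `t` (trial indices), `probe` (logical matrix flagging the
#'   zero-error-clamp probe trials on which adaptation is measurable during
#'   training; all retention trials are flagged), `truth` (data frame of
#'   per-subject `a`, `b`, `tau`, `lam`), `pop`, and `seed`. Convert to a
#'   tidy per-trial table with [as.data.frame()].
#' @export
simulate_cohort <- function(pop, drift = NULL, seed = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  seed <- resolve_seed(seed)
  n <- pop$n_subjects
  seeds <- derive_seeds(seed, n)
  t <- trial_index(pop$n_training, pop$n_retention)
  n_tr <- pop$n_training
  n_probe <- round(pop$probe_frac * n_tr)
  values <- matrix(NA_real_, n, length(t))
  probe <- matrix(TRUE, n, length(t))
  truth <- matrix(NA_real_, n, 4L,
                  dimnames = list(NULL, c("a", "b", "tau", "lam")))
  for (i in seq_len(n)) {
    values[i, ] <- with_seed(seeds[i], function() {
      p <- draw_subject(pop)
      truth[i, ] <<- c(p$a, p$b, p$tau, p$lam)
      y <- dexp_eval(p$a, p$b, p$tau, p$lam, t)
      noise <- if (is.null(drift)) {
        stats::rnorm(length(t), 0, pop$noise_sd)
      } else {
        c(stats::rnorm(pop$n_training, 0, pop$noise_sd),
          arma_recursion(drift$ar, drift$ma,
                         stats::rnorm(pop$n_retention, 0, drift$eps_sd)))
      }
      if (n_probe < n_tr) {
        mask <- logical(n_tr)
        mask[sample.int(n_tr, n_probe)] <- TRUE
        probe[i, seq_len(n_tr)] <<- mask
      }
      y + noise
    })
  }
  structure(list(values = values, t = t, probe = probe,
                 truth = as.data.frame(truth), pop = pop, seed = seed),
            class = "decay_cohort")
}

#' @export
print.decay_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects x %d trials (%d training + %d retention)\n",
              nrow(x$values), ncol(x$values),
              sum(x$t <= 0L), sum(x$t > 0L)))
  invisible(x)
}

#' Convert a simulated cohort to a tidy per-trial table
#'
#' @param x A `decay_cohort`.
#' @param ... Unused.
#' @return A `trial_series` data frame stacking all subjects, with columns
#'   `subject_id`, `t`, `phase`, `probe`, `value`.
#' @export
as.data.frame.decay_cohort <- function(x, ...) {
  n <- nrow(x$values)
  ids <- sprintf("s%03d", seq_len(n))
  phase <- ifelse(x$t <= 0L, "training", "retention")
  probe_lab <- if (is.null(x$probe)) NA_character_ else
    ifelse(as.vector(t(x$probe)) & rep(phase, times = n) == "training",
           "zEC", NA_character_)
  out <- data.frame(
    subject_id = rep(ids, each = length(x$t)),
    t = rep(x$t, times = n),
    phase = rep(phase, times = n),
    probe = probe_lab,
    value = as.vector(t(x$values)),
    stringsAsFactors = FALSE)
  class(out) <- c("trial_series", "data.frame")
  out
}

#' Extract one subject's series from a cohort
#' @param cohort A `decay_cohort`.
#' @param i Subject row index.
#' @return A `trial_series` data frame for subject `i`.
#' @export
cohort_subject <- function(cohort, i) {
  stopifnot(inherits(cohort, "decay_cohort"))
  tr <- cohort$truth[i, ]
  new_trial_series(sprintf("s%03d", i), cohort$t, cohort$values[i, ],
                   truth = delayed_exp_params(tr$a, tr$b, tr$tau, tr$lam))
}
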