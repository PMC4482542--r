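#' Curl force field specification
#'
#' Velocity-dependent perturbation `F = B v` with antisymmetric
#' `B = [[0, b], [-b, 0]]` (b in N s/m). The force is orthogonal to the
#' velocity for every velocity, so the field does net zero work.
#'
#' @param gain_b Curl gain in N s/m; +15 and -15 are the trained fields.
#' @return An object of class `force_field_spec` with elements `gain_b` and
#'   the 2x2 matrix `B`.
#' @export
force_field_spec <- function(gain_b = 15) {
  stopifnot_scalar(gain_b, "gain_b")
  structure(list(gain_b = gain_b,
                 B = matrix(c(0, -gain_b, gain_b, 0), 2L, 2L)),
            class = "force_field_spec")
}

#' Curl-field force for a set of velocities
#'
#' @param vel_xy n x 2 matrix of velocities (m/s).
#' @param ff A [force_field_spec()].
#' @return n x 2 matrix of forces `F = B v` (N).
#' @export
curl_force <- function(vel_xy, ff) {
  vel_xy <- rbind(vel_xy)
  t(ff$B %*% t(vel_xy))
}

#' Ideal compensatory lateral force profile
#'
#' For a forward movement in a curl field the perturbing force is lateral,
#' proportional to forward velocity; full compensation requires
#' `F_lat(t) = gain_b * v_forward(t)`.
#'
#' @param vel_forward Forward velocity trace (m/s).
#' @param ff A [force_field_spec()].
#' @return Lateral force trace (N).
#' @export
ideal_force_profile <- function(vel_forward, ff) {
  if (!all(is.finite(vel_forward))) stop("velocities must be finite")
  ff$gain_b * vel_forward
}

#' Adaptation coefficient of a measured force profile
#'
#' Through-origin least-squares slope of the measured lateral force on the
#' ideal compensatory force for the positive field: the ideal profile itself
#' scores +1 and perfect compensation of the negative field scores -1. The
#' through-origin form makes the score a pure gain on the ideal shape; an
#' intercept can be admitted for sensitivity checks.
#'
#' @param measured Measured lateral force trace (N).
#' @param ideal_pos Ideal +FF compensatory trace (N); must not be
#'   identically zero.
#' @param intercept Logical; include an intercept in the regression.
#' @return Scalar regression slope.
#' @export
adaptation_coefficient <- function(measured, ideal_pos, intercept = FALSE) {
  if (length(measured) != length(ideal_pos)) stop("traces must have equal length")
  if (all(ideal_pos == 0)) stop("undefined measure: ideal force is identically zero")
  if (intercept) {
    unname(stats::coef(stats::lm(measured ~ ideal_pos))[2L])
  } else {
    sum(measured * ideal_pos) / sum(ideal_pos^2)
  }
}

#' Integrated lateral force measure
#'
#' Ratio of the time-integrals (trapezoidal, uniform 200 Hz grid by
#' default) of the measured and ideal lateral force profiles. Insensitive
#' to the within-trial timing and shape of the force: any equal-area
#' profile scores the same.
#'
#' @param measured,ideal_pos Lateral force traces (N), equal length.
#' @param dt Sample spacing in seconds.
#' @return Scalar integral ratio.
#' @export
integrated_lateral_force <- function(measured, ideal_pos, dt = 1 / 200) {
  if (length(measured) != length(ideal_pos)) stop("traces must have equal length")
  denom <- trapz_uniform(ideal_pos, dt)
  if (abs(denom) < .Machine$double.eps * 100)
    stop("undefined measure: ideal force integrates to zero")
  trapz_uniform(measured, dt) / denom
}

#' Reference traces to a null-field control cohort
#'
#' Subtracts the trial-aligned control mean (from a 0-FF cohort) from each
#' trace, isolating learning-related changes from block-position biases
#' that are shared with the control.
#'
#' @param traces Numeric vector, or matrix with one row per subject and one
#'   column per trial.
#' @param control_mean Control-cohort mean with the same per-trial
#'   structure (vector of length `ncol(traces)`).
#' @return Referenced traces, same shape as `traces`.
#' @export
control_reference <- function(traces, control_mean) {
  if (is.matrix(traces)) {
    if (ncol(traces) != length(control_mean))
      stop("alignment mismatch between traces and control mean")
    sweep(traces, 2L, control_mean)
  } else {
    if (length(traces) != length(control_mean))
      stop("alignment mismatch between traces and control mean")
    traces - control_mean
  }
}

#' Balanced overall decay with bootstrap uncertainty
#'
#' For an experiment balanced across field directions, overall decay is
#' `((LP - LN) - (RP - RN)) / (LP - LN)` where LP/LN are the positive and
#' negative subgroup means of asymptotic learning (per-subject means over
#' the last 150 training trials, computed upstream) and RP/RN the subgroup
#' means of asymptotic retention (retention trials after the first 150).
#' Differencing the subgroups cancels any shared baseline bias. The
#' standard error is a subject-level bootstrap, resampling subjects with
#' replacement within each subgroup.
#'
#' @param learning Per-subject asymptotic learning values.
#' @param retention Per-subject asymptotic retention values.
#' @param group Per-subject labels, `"P"` (positive field) or `"N"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `decay_summary` list: `LP`, `LN`, `RP`, `RN`, `overall_decay`,
#'   `boot_se`, `n_boot`.
#' @export
overall_decay <- function(learning, retention, group, n_boot = 1e4,
                          seed = NULL) {
  stopifnot(length(learning) == length(retention),
            length(learning) == length(group))
  if (!all(group %in% c("P", "N"))) stop("group labels must be 'P' or 'N'")
  ip <- which(group == "P"); inn <- which(group == "N")
  if (length(ip) == 0L || length(inn) == 0L)
    stop("both subgroups must be non-empty")
  stat <- function(p_idx, n_idx) {
    LP <- mean(learning[p_idx]); LN <- mean(learning[n_idx])
    RP <- mean(retention[p_idx]); RN <- mean(retention[n_idx])
    if (LP == LN) stop("no learning separation: LP equals LN")
    c(LP = LP, LN = LN, RP = RP, RN = RN,
      decay = ((LP - LN) - (RP - RN)) / (LP - LN))
  }
  full <- stat(ip, inn)
  seed <- resolve_seed(seed)
  boots <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(i) {
      stat(ip[sample.int(length(ip), length(ip), replace = TRUE)],
           inn[sample.int(length(inn), length(inn), replace = TRUE)])[["decay"]]
    }, numeric(1L))
  })
  structure(list(LP = full[["LP"]], LN = full[["LN"]],
                 RP = full[["RP"]], RN = full[["RN"]],
                 overall_decay = full[["decay"]],
                 boot_se = stats::sd(boots), n_boot = n_boot),
            class = "decay_summary")
}

#' @export
print.decay_summary <- function(x, ...) {
  cat(sprintf(
    "Overall decay: %.3f (bootstrap SE %.3f, %d resamples)\n  LP = %.3f, LN = %.3f, RP = %.3f, RN = %.3f\n",
    x$overall_decay, x$boot_se, as.integer(x$n_boot),
    x$LP, x$LN, x$RP, x$RN))
  invisible(x)
}

#' Per-subject learning and retention window means
#'
#' Convenience extractor feeding [overall_decay()]: asymptotic learning is
#' each subject's mean over the last `learning_window` training trials and
#' asymptotic retention the mean over retention trials after the first
#' `retention_skip`.
#'
#' @param cohort A `decay_cohort`.
#' @param learning_window Trials of late training averaged (150 by default;
#'   100 for the point-to-point zero-clamp configuration).
#' @param retention_skip Retention trials discarded before averaging.
#' @return Data frame with columns `subject`, `learning`, `retention`.
#' @export
asymptote_measures <- function(cohort, learning_window = 150L,
                               retention_skip = 150L) {
  stopifnot(inherits(cohort, "decay_cohort"))
  t <- cohort$t
  learn_cols <- which(t <= 0L & t > -learning_window)
  ret_cols <- which(t > retention_skip)
  data.frame(subject = seq_len(nrow(cohort$values)),
             learning = rowMeans(cohort$values[, learn_cols, drop = FALSE]),
             retention = rowMeans(cohort$values[, ret_cols, drop = FALSE]))
}
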