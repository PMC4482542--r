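#' Median-divide a cohort by early decay
#'
#' Scores each subject by normalized decay over the decision window —
#' `(mean of last 50 training trials - mean of first 50 retention trials) /
#' mean of last 50 training trials` — and splits the cohort at the median
#' score. Subjects at or above the median form the high-decay subgroup, so
#' with odd `n` the median subject joins the high-decay side. Subjects with
#' near-zero asymptotic learning (denominator below `learning_floor`) are
#' excluded with a warning; set `normalize = FALSE` to score by the raw
#' (unnormalized) drop instead.
#'
#' The learning level is each subject's mean over the *measured* trials of
#' the window: during force-field training adaptation is only observable on
#' the interspersed zero-error-clamp probe trials (the `probe` mask of the
#' cohort), so by default only those enter the mean. Retention trials are
#' all error clamps and all enter.
#'
#' @param cohort A `decay_cohort`.
#' @param decision_window Retention trials entering the decay score.
#' @param learning_window Late-training trials entering the score.
#' @param normalize Divide the drop by the subject's own learning level.
#' @param learning_floor Exclusion threshold on |learning| when normalizing.
#' @param use_probes Restrict training-window means to probe trials when the
#'   cohort carries a probe mask.
#' @return List with integer index vectors `high` and `low`, the per-subject
#'   `scores` and `learning` levels, and `excluded` indices.
#' @export
median_divide <- function(cohort, decision_window = 50L,
                          learning_window = 50L, normalize = TRUE,
                          learning_floor = 1e-6, use_probes = TRUE) {
  stopifnot(inherits(cohort, "decay_cohort"))
  t <- cohort$t
  early_cols <- which(t >= 1L & t <= decision_window)
  learning <- measured_learning(cohort, learning_window, use_probes)
  early <- rowMeans(cohort$values[, early_cols, drop = FALSE])
  excluded <- integer(0L)
  if (normalize) {
    excluded <- which(abs(learning) < learning_floor)
    if (length(excluded) > 0L)
      warning(sprintf("%d subject(s) excluded for near-zero learning",
                      length(excluded)))
    scores <- (learning - early) / learning
    scores[excluded] <- NA_real_
  } else {
    scores <- learning - early
  }
  ok <- which(!is.na(scores))
  # top half by score forms the high-decay subgroup; with odd n the median
  # subject joins it; score ties are broken by subject index so fully
  # degenerate cohorts still split into equal halves deterministically
  ord <- ok[order(scores[ok], seq_along(ok), decreasing = c(TRUE, FALSE),
                  method = "radix")]
  n_high <- ceiling(length(ok) / 2)
  high <- sort(ord[seq_len(n_high)])
  low <- sort(ord[-seq_len(n_high)])
  list(high = high, low = low, scores = scores, learning = learning,
       excluded = excluded)
}

# Per-subject mean over the measured trials of the last-`window` training
# trials: probe trials only when a probe mask is present (training-phase
# adaptation is unobservable on force-field trials).
measured_learning <- function(cohort, window = 50L, use_probes = TRUE) {
  t <- cohort$t
  cols <- which(t <= 0L & t > -window)
  vals <- cohort$values[, cols, drop = FALSE]
  if (!use_probes || is.null(cohort$probe)) return(rowMeans(vals))
  mask <- cohort$probe[, cols, drop = FALSE]
  vapply(seq_len(nrow(vals)), function(i) {
    m <- mask[i, ]
    if (!any(m)) mean(vals[i, ]) else mean(vals[i, m])
  }, numeric(1L))
}

#' Early-decay-ratio pair of a median-divided cohort
#'
#' Computes the early decay ratio of the high- and low-decay subgroups. In
#' the default `"mean_trace"` mode the ratio is taken on each subgroup's
#' subject-averaged trace, with the learning level the subgroup mean of the
#' per-subject measured (probe-trial) learning levels — the stable
#' convention used throughout the group analysis. The `"per_subject"` mode
#' instead averages each subject's own ratio; individual denominators are
#' noisy, so this mode is heavy-tailed and provided for sensitivity
#' analysis (subjects whose denominator falls below `floor` are dropped).
#'
#' @param cohort A `decay_cohort`.
#' @param split Optional result of [median_divide()]; computed if missing.
#' @param early_window,late_window,learning_window Window lengths (trials).
#' @param floor Smallest accepted |learning - late retention|.
#' @param mode `"mean_trace"` or `"per_subject"`.
#' @return Named numeric `c(ed_high, ed_low)`.
#' @export
cohort_ed_pair <- function(cohort, split = NULL, early_window = 50L,
                           late_window = 75L, learning_window = 50L,
                           floor = 1e-6, mode = c("mean_trace", "per_subject")) {
  stopifnot(inherits(cohort, "decay_cohort"))
  mode <- match.arg(mode)
  split <- split %||% median_divide(cohort, learning_window = learning_window)
  t <- cohort$t
  tmax <- max(t)
  learning <- split$learning %||%
    measured_learning(cohort, learning_window)
  early_cols <- t >= 1L & t <= early_window
  late_cols <- t > tmax - late_window
  one <- function(idx) {
    if (mode == "mean_trace") {
      m <- colMeans(cohort$values[idx, , drop = FALSE])
      L <- mean(learning[idx])
      denom <- L - mean(m[late_cols])
      if (abs(denom) < floor)
        stop("undefined early decay ratio: learning and late retention coincide")
      (L - mean(m[early_cols])) / denom
    } else {
      ratios <- vapply(idx, function(i) {
        denom <- learning[i] - mean(cohort$values[i, late_cols])
        if (abs(denom) < floor) return(NA_real_)
        (learning[i] - mean(cohort$values[i, early_cols])) / denom
      }, numeric(1L))
      mean(ratios, na.rm = TRUE)
    }
  }
  c(ed_high = one(split$high), ed_low = one(split$low))
}

#' Early decay ratio of a mean retention trace
#'
#' `(learning - early retention) / (learning - late retention)` where
#' learning is the mean over the last `learning_window` training trials,
#' early retention the mean over the first `early_window` retention trials,
#' and late retention the mean over the last `late_window` retention
#' trials. Near 1 indicates immediate, complete early decay; near 0, decay
#' deferred past the early window; the noise-selection bias of median
#' division can push a low-decay subgroup slightly negative.
#'
#' @param trace Mean adaptation trace (one value per trial).
#' @param t Trial indices aligned with `trace` (0 = last training trial).
#' @param learning_window,early_window,late_window Window lengths in trials.
#' @param floor Smallest |learning - late retention| accepted.
#' @return Scalar early decay ratio.
#' @export
early_decay_ratio <- function(trace, t, learning_window = 50L,
                              early_window = 50L, late_window = 75L,
                              floor = 1e-6) {
  stopifnot(length(trace) == length(t))
  learning <- mean(trace[t <= 0L & t > -learning_window])
  early <- mean(trace[t >= 1L & t <= early_window])
  tmax <- max(t)
  late <- mean(trace[t > tmax - late_window])
  denom <- learning - late
  if (abs(denom) < floor)
    stop("undefined early decay ratio: learning and late retention coincide")
  (learning - early) / denom
}

#' Simulate the sampling distribution of early-decay-ratio pairs
#'
#' Repeatedly simulates a cohort at mean onset delay `mu_lambda`,
#' median-divides it, and computes the early decay ratio of each subgroup's
#' mean trace.
#'
#' @param mu_lambda Mean of the exponential onset-delay distribution
#'   (trials).
#' @param pop A [population_spec()]; its `mu_lambda` is overridden.
#' @param n_sims Number of simulated cohorts.
#' @param seed Integer master seed; per-simulation child seeds are derived
#'   deterministically.
#' @return Data frame with columns `ed_high`, `ed_low` (one row per
#'   simulation).
#' @export
simulate_ed_distribution <- function(mu_lambda, pop = population_spec(),
                                     n_sims = 1000L, seed = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  pop$mu_lambda <- mu_lambda
  seed <- resolve_seed(seed)
  seeds <- derive_seeds(seed, n_sims)
  ed_high <- numeric(n_sims)
  ed_low <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    cohort <- simulate_cohort(pop, seed = seeds[s])
    pair <- cohort_ed_pair(cohort)
    ed_high[s] <- pair[["ed_high"]]
    ed_low[s] <- pair[["ed_low"]]
  }
  data.frame(ed_high = ed_high, ed_low = ed_low)
}

#' Fit a multivariate normal to simulated ratio pairs
#'
#' Sample mean and unbiased sample covariance of the `(ed_high, ed_low)`
#' pairs; a near-singular covariance is regularized with a 1e-8 diagonal
#' jitter so the density stays evaluable.
#'
#' @param pairs Data frame or matrix with columns `ed_high`, `ed_low`
#'   (>= 10 rows).
#' @return List with `mean`, `cov`, and `log_density(x)` evaluating the
#'   bivariate normal log-density at a length-2 vector.
#' @export
fit_mvn <- function(pairs) {
  x <- as.matrix(pairs)[, c("ed_high", "ed_low"), drop = FALSE]
  if (nrow(x) < 10L) stop("need at least 10 pairs")
  mu <- colMeans(x)
  S <- stats::cov(x)
  if (!is.finite(determinant(S)$modulus) ||
      determinant(S)$modulus < log(1e-12))
    S <- S + diag(1e-8, 2L)
  Sinv <- solve(S)
  logdet <- as.numeric(determinant(S)$modulus)
  log_density <- function(x) {
    d <- as.numeric(x) - mu
    -log(2 * pi) - logdet / 2 - as.numeric(t(d) %*% Sinv %*% d) / 2
  }
  list(mean = mu, cov = S, log_density = log_density)
}

hpd_discrete <- function(grid, prob, level) {
  ord <- order(prob, decreasing = TRUE)
  k <- which(cumsum(prob[ord]) >= level)[1L]
  sel <- grid[sort(ord[seq_len(k)])]
  c(lo = min(sel), hi = max(sel))
}

#' Posterior over the population mean decay-onset delay
#'
#' Simulation-based (likelihood-free) inference: for each candidate mean
#' delay on the grid, `n_sims` cohorts are simulated, the joint sampling
#' distribution of the subgroup early decay ratios is summarized by a
#' bivariate normal, and its density at the observed pair gives the
#' likelihood. A discrete uniform prior over the grid then yields the
#' posterior, its maximum a posteriori value, and highest-posterior-density
#' credible sets (smallest sets of grid points holding at least 95% and 99%
#' mass, reported by their min/max).
#'
#' Each grid value uses an independent deterministic child stream of
#' `seed`, so the likelihood surface is reproducible.
#'
#' @param observed Length-2 numeric `c(ed_high, ed_low)` (or a list/data
#'   frame row with those names): the observed early decay ratios.
#' @param pop A [population_spec()] describing the simulated cohorts
#'   (subject count matching the experiment being analyzed).
#' @param grid Candidate integer mean delays (trials).
#' @param n_sims Simulations per grid value.
#' @param seed Integer master seed.
#' @return A `mean_delay_posterior`: list with `grid`, `prob`,
#'   `log_likelihood`, `map`, `hpd95`, `hpd99`, `observed`, `n_sims`.
#' @export
posterior_mean_delay <- function(observed, pop = population_spec(),
                                 grid = 0:90, n_sims = 1000L, seed = NULL) {
  if (is.list(observed)) observed <- c(observed$ed_high, observed$ed_low)
  observed <- as.numeric(observed)
  if (length(observed) != 2L || !all(is.finite(observed)))
    stop("`observed` must be two finite values (ed_high, ed_low)")
  seed <- resolve_seed(seed)
  seeds <- derive_seeds(seed, length(grid))
  loglik <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pairs <- simulate_ed_distribution(grid[i], pop, n_sims = n_sims,
                                      seed = seeds[i])
    loglik[i] <- fit_mvn(pairs)$log_density(observed)
  }
  shifted <- loglik - max(loglik)
  w <- exp(shifted)
  if (!any(is.finite(shifted)) || sum(w) == 0) {
    warning("all likelihoods numerically zero; returning flat posterior")
    w <- rep(1, length(grid))
  }
  prob <- w / sum(w)
  structure(list(grid = grid, prob = prob, log_likelihood = loglik,
                 map = grid[which.max(prob)],
                 hpd95 = hpd_discrete(grid, prob, 0.95),
                 hpd99 = hpd_discrete(grid, prob, 0.99),
                 observed = c(ed_high = observed[1L], ed_low = observed[2L]),
                 n_sims = n_sims, seed = seed),
            class = "mean_delay_posterior")
}

#' @export
print.mean_delay_posterior <- function(x, ...) {
  cat(sprintf(
    paste0("Posterior over mean decay-onset delay (grid %d..%d, %d sims/point)\n",
           "  observed ED pair: high %.2f, low %.2f\n",
           "  MAP = %d trials; 95%% HPD [%d, %d]; 99%% HPD [%d, %d]\n"),
    min(x$grid), max(x$grid), as.integer(x$n_sims),
    x$observed[["ed_high"]], x$observed[["ed_low"]],
    x$map, x$hpd95[["lo"]], x$hpd95[["hi"]],
    x$hpd99[["lo"]], x$hpd99[["hi"]]))
  invisible(x)
}

#' Analytic facts about an exponential delay distribution
#'
#' For onset delays distributed exponentially with the given mean:
#' the fraction of subjects with delays below / above a cutoff and the
#' distribution median (`mean * log 2`). A zero mean denotes a point mass
#' at zero (every subject decays immediately).
#'
#' @param mean Mean delay in trials (>= 0).
#' @return List with functions `fraction_below(t)`, `fraction_above(t)` and
#'   the scalar `median`.
#' @export
exp_delay_facts <- function(mean) {
  stopifnot_scalar(mean, "mean")
  if (mean < 0) stop("`mean` must be >= 0")
  if (mean == 0) {
    list(fraction_below = function(t) as.numeric(t >= 0),
         fraction_above = function(t) as.numeric(t < 0),
         median = 0)
  } else {
    list(fraction_below = function(t) 1 - exp(-t / mean),
         fraction_above = function(t) exp(-t / mean),
         median = mean * log(2))
  }
}
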