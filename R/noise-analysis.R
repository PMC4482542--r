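#' Remove the across-subject mean from retention traces
#'
#' Focuses drift analysis on individual fluctuations rather than the shared
#' mean decay: per trial from `start_trial` onward, the across-subject mean
#' is subtracted, leaving residual traces whose column means are exactly
#' zero.
#'
#' @param traces Matrix, one row per subject, one column per trial.
#' @param t Trial indices aligned with the columns.
#' @param start_trial First retention trial retained (76 by default,
#'   skipping the steep part of the mean decay).
#' @return Residual matrix (subjects x retained trials) with the retained
#'   trial indices in `attr(, "t")`.
#' @export
demean_across_subjects <- function(traces, t, start_trial = 76L) {
  if (!is.matrix(traces)) stop("`traces` must be a subjects x trials matrix")
  if (ncol(traces) != length(t)) stop("trial index misaligned with traces")
  if (nrow(traces) < 2L) stop("need at least 2 subjects")
  keep <- which(t >= start_trial)
  x <- traces[, keep, drop = FALSE]
  out <- sweep(x, 2L, colMeans(x))
  attr(out, "t") <- t[keep]
  out
}

# Full-overlap lag-k Pearson correlation: correlate x[(k+1):n] with
# x[1:(n-k)], each segment demeaned by its own mean.
lag_correlation <- function(x, k) {
  n <- length(x)
  stats::cor(x[(k + 1L):n], x[1L:(n - k)])
}

#' Autocorrelation profile of a trace
#'
#' Lagged Pearson correlations under the full-overlap convention: lag `k`
#' correlates the series against itself shifted by `k`, using only the
#' overlapping stretch, with each segment's own mean removed. Lag 0 is
#' identically 1.
#'
#' @param trace Numeric series (longer than `max_lag + 1`).
#' @param max_lag Largest lag computed.
#' @return A `correlation_profile`: list with `lags` (0..max_lag), `acf`,
#'   `pacf` (`NULL` here; see [partial_autocorrelation()]), `n`.
#' @export
autocorrelation <- function(trace, max_lag = 10L) {
  n <- length(trace)
  if (n <= max_lag + 1L) stop("series too short for requested max_lag")
  if (stats::sd(trace) == 0) stop("undefined correlation for a constant series")
  acf <- c(1, vapply(seq_len(max_lag), function(k) lag_correlation(trace, k),
                     numeric(1L)))
  structure(list(lags = 0L:max_lag, acf = acf, pacf = NULL, n = n),
            class = "correlation_profile")
}

#' Partial autocorrelation profile of a trace
#'
#' The lag-k partial autocorrelation is the coefficient on the lag-k term
#' when regressing `x(t)` jointly on `x(t-1) ... x(t-k)`; it is computed
#' here by solving the Yule-Walker normal equations built from the
#' full-overlap autocorrelations of [autocorrelation()], the stationary
#' form of that regression. `pacf(1)` equals `acf(1)` exactly.
#'
#' @param trace Numeric series.
#' @param max_lag Largest lag computed.
#' @return A `correlation_profile` with both `acf` (lags 0..max_lag) and
#'   `pacf` (lags 1..max_lag).
#' @export
partial_autocorrelation <- function(trace, max_lag = 10L) {
  prof <- autocorrelation(trace, max_lag)
  r <- prof$acf
  pacf <- vapply(seq_len(max_lag), function(k) {
    R <- stats::toeplitz(r[1L:k])
    phi <- solve(R, r[2L:(k + 1L)])
    phi[k]
  }, numeric(1L))
  prof$pacf <- pacf
  prof
}

#' Fit an ARMA(1,1) model to a (demeaned) residual trace
#'
#' Conditional least squares (zero initial innovation) by default, via
#' `stats::arima` with no mean term; supply `method = "ml"` for full
#' maximum likelihood. Input is expected to be demeaned (e.g. by
#' [demean_across_subjects()]); the fit is then invariant to adding a
#' constant before demeaning.
#'
#' @param trace Numeric residual series, length >= 50.
#' @param method `"css"` (conditional least squares) or `"ml"`.
#' @return An [arma_spec()] estimate with the innovation sd in `eps_sd`
#'   and a logical `attr(, "converged")`.
#' @export
fit_arma11 <- function(trace, method = c("css", "ml")) {
  method <- match.arg(method)
  if (length(trace) < 50L) stop("series must have at least 50 values")
  fit <- tryCatch(
    stats::arima(trace, order = c(1L, 0L, 1L), include.mean = FALSE,
                 method = if (method == "css") "CSS" else "ML"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressWarnings(
        stats::arima(trace, order = c(1L, 0L, 1L), include.mean = FALSE,
                     method = if (method == "css") "CSS" else "ML")),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    out <- arma_spec(0, 0, stats::sd(trace))
    attr(out, "converged") <- FALSE
    return(out)
  }
  co <- stats::coef(fit)
  ar <- unname(co[["ar1"]])
  if (abs(ar) >= 1) ar <- sign(ar) * (1 - 1e-8)
  out <- arma_spec(ar, unname(co[["ma1"]]), sqrt(fit$sigma2))
  attr(out, "converged") <- is.null(fit$code) || fit$code == 0L
  out
}

#' Drift descriptors for every subject in a cohort
#'
#' Per subject: decay depth and rate from a zero-delay exponential fit,
#' retention-residual noise sd, ARMA(1,1) coefficients, and the first three
#' partial autocorrelations of the demeaned retention residuals. Subjects
#' whose residual series is shorter than 50 trials are excluded with a
#' warning.
#'
#' @param cohort A `decay_cohort`.
#' @param start_trial First retention trial entering the drift analysis.
#' @return Data frame with one row per subject: `subject`, `decay_depth`
#'   (a - b), `decay_rate` (tau), `retention_sd`, `ar`, `ma`, `eps_sd`,
#'   `pac1`, `pac2`, `pac3`.
#' @export
drift_descriptors <- function(cohort, start_trial = 76L) {
  stopifnot(inherits(cohort, "decay_cohort"))
  resid <- demean_across_subjects(cohort$values, cohort$t, start_trial)
  if (ncol(resid) < 50L) {
    warning("residual series shorter than 50 trials; no ARMA fits")
    return(data.frame())
  }
  cons <- fit_constraints(lam_bounds = c(-1e-6, 1e-6))
  n <- nrow(cohort$values)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fit_delayed_exponential(
      data.frame(t = cohort$t, value = cohort$values[i, ]),
      constraints = cons)
    r <- resid[i, ]
    am <- fit_arma11(r)
    pac <- partial_autocorrelation(r, 3L)$pacf
    rows[[i]] <- data.frame(
      subject = i, decay_depth = f$params$a - f$params$b,
      decay_rate = f$params$tau, retention_sd = stats::sd(r),
      ar = am$ar, ma = am$ma, eps_sd = am$eps_sd,
      pac1 = pac[1L], pac2 = pac[2L], pac3 = pac[3L])
  }
  do.call(rbind, rows)
}

#' Compare drift descriptor populations
#'
#' Aligned summary statistics (and shared-break histogram counts) for two
#' collections of per-subject drift descriptors, e.g. a data cohort versus
#' a simulated one.
#'
#' @param fits_a,fits_b Data frames of descriptors sharing numeric columns
#'   (e.g. from [drift_descriptors()]).
#' @param quantities Columns to compare; defaults to all shared numeric
#'   columns except `subject`.
#' @param n_breaks Histogram bin count.
#' @return List with `summary` (quantity, group, n, mean, sd, quartiles)
#'   and `histograms` (per quantity: shared `breaks`, counts `a` and `b`).
#' @export
population_comparison <- function(fits_a, fits_b, quantities = NULL,
                                  n_breaks = 15L) {
  if (nrow(fits_a) == 0L || nrow(fits_b) == 0L)
    stop("both collections must be non-empty")
  shared <- intersect(names(fits_a), names(fits_b))
  num <- shared[vapply(fits_a[shared], is.numeric, logical(1L))]
  quantities <- quantities %||% setdiff(num, "subject")
  summ <- do.call(rbind, lapply(quantities, function(q) {
    do.call(rbind, lapply(list(a = fits_a, b = fits_b), function(d) {
      x <- d[[q]]
      data.frame(quantity = q, n = length(x), mean = mean(x),
                 sd = stats::sd(x),
                 q25 = unname(stats::quantile(x, 0.25)),
                 q50 = unname(stats::quantile(x, 0.50)),
                 q75 = unname(stats::quantile(x, 0.75)))
    }))
  }))
  summ$group <- rep(c("a", "b"), times = length(quantities))
  rownames(summ) <- NULL
  hists <- lapply(quantities, function(q) {
    rng <- range(c(fits_a[[q]], fits_b[[q]]))
    breaks <- seq(rng[1L], rng[2L], length.out = n_breaks + 1L)
    list(breaks = breaks,
         a = graphics::hist(fits_a[[q]], breaks = breaks, plot = FALSE)$counts,
         b = graphics::hist(fits_b[[q]], breaks = breaks, plot = FALSE)$counts)
  })
  names(hists) <- quantities
  list(summary = summ, histograms = hists)
}
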