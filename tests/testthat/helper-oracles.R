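# Independent oracles used across the test files.

# Durbin-Levinson recursion for partial autocorrelations from an
# autocorrelation sequence r (r[1] = lag 0 = 1). Independent of the
# Yule-Walker solve used by the package.
durbin_levinson_pacf <- function(r, max_lag) {
  phi_prev <- numeric(0)
  pacf <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      phi_k <- r[2L]
    } else {
      num <- r[k + 1L] - sum(phi_prev * r[k:2L])
      den <- 1 - sum(phi_prev * r[2L:k])
      phi_k <- num / den
    }
    pacf[k] <- phi_k
    phi_prev <- if (k == 1L) phi_k else c(phi_prev - phi_k * rev(phi_prev), phi_k)
  }
  pacf
}

# Closed-form mean of exp(-t/tau) over integer trials lo..hi.
mean_exp_window <- function(tau, lo, hi) {
  mean(exp(-(lo:hi) / tau))
}

# Batch evaluation of the vEC rejection rules on a len x B matrix of
# candidate angle sequences (one per column). Returns a logical vector of
# acceptances. Written independently of passes_criteria (flattened-cumsum
# moving sums; the cross-column terms cancel in the window differences) and
# cross-validated against it in the acceptance suite before being used to
# estimate the acceptance rate at scale.
vec_batch_accept <- function(A, criteria) {
  len <- nrow(A); B <- ncol(A)
  lat <- criteria$movement_length * sin(A * pi / 180)
  P <- matrix(0L, len, B)
  P[lat > criteria$hit_lateral_max] <- 1L
  P[lat < -criteria$hit_lateral_max] <- -1L
  flat <- cumsum(c(0L, as.vector(P)))
  win_sums <- function(w) {
    starts <- as.vector(outer(0L:(len - w), (0L:(B - 1L)) * len, `+`)) + 1L
    matrix(flat[starts + w] - flat[starts], len - w + 1L, B)
  }
  breach5 <- colSums(abs(win_sums(5L)) > 5 * criteria$smooth5_max) > 0L
  breach9 <- colSums(abs(win_sums(9L)) > 9 * criteria$smooth9_max) > 0L
  ok <- !(breach5 | breach9)
  for (j in which(ok)) {
    pos <- which(P[, j] != 0L)
    g <- if (length(pos)) max(diff(c(0L, pos, len + 1L))) else Inf
    if (g > criteria$max_gap) ok[j] <- FALSE
  }
  ok
}

# Noise-free delayed exponential series as a plain data frame.
clean_series <- function(a, b, tau, lam, n_training = 300, n_retention = 325) {
  t <- trial_index(n_training, n_retention)
  data.frame(t = t,
             value = eval_delayed_exponential(
               delayed_exp_params(a, b, tau, lam), t))
}
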