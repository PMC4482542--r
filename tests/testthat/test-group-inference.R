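test_that("median division separates decayers from non-decayers", {
  # build a cohort by hand: 3 immediate full decayers, 3 non-decayers
  t <- trial_index(100, 150)
  vals <- rbind(matrix(rep(ifelse(t <= 0, 1, 0), 3), 3, byrow = TRUE),
                matrix(1, 3, length(t)))
  co <- structure(list(values = vals, t = t, probe = NULL, truth = NULL),
                  class = "decay_cohort")
  sp <- median_divide(co)
  expect_setequal(sp$high, 1:3)
  expect_setequal(sp$low, 4:6)
  # even split sizes for n = 40
  co40 <- simulate_cohort(population_spec(), seed = 1)
  sp40 <- median_divide(co40)
  expect_equal(length(sp40$high), 20)
  expect_equal(length(sp40$low), 20)
  # odd n: the median subject joins the high-decay subgroup
  co41 <- simulate_cohort(population_spec(n_subjects = 41), seed = 2)
  sp41 <- median_divide(co41)
  expect_equal(length(sp41$high), 21)
  expect_equal(length(sp41$low), 20)
})

test_that("near-zero learners are excluded with a warning", {
  t <- trial_index(60, 60)
  vals <- rbind(ifelse(t <= 0, 1, 0.5), ifelse(t <= 0, 0.9, 0.4),
                rep(0, length(t)), ifelse(t <= 0, 1.1, 0.6))
  co <- structure(list(values = vals, t = t, probe = NULL),
                  class = "decay_cohort")
  expect_warning(sp <- median_divide(co), "near-zero learning")
  expect_equal(sp$excluded, 3L)
  expect_false(3L %in% c(sp$high, sp$low))
})

test_that("early decay ratio matches closed-form window means", {
  # immediate complete step decay: ratio is exactly 1
  t <- trial_index(100, 325)
  step <- ifelse(t <= 0, 1, 0)
  expect_equal(early_decay_ratio(step, t), 1)
  # decay starting only after trial 50: zero early decay
  late_only <- ifelse(t <= 50, 1, 0)
  expect_equal(early_decay_ratio(late_only, t), 0)
  # noiseless exponential against the analytic window means
  a <- 0.875; b <- 0.36; tau <- 40
  tr <- eval_delayed_exponential(delayed_exp_params(a, b, tau, 0), t)
  e50 <- b + (a - b) * mean_exp_window(tau, 1, 50)
  l75 <- b + (a - b) * mean_exp_window(tau, 251, 325)
  expect_equal(early_decay_ratio(tr, t), (a - e50) / (a - l75),
               tolerance = 1e-12)
  # degenerate denominator errors out
  expect_error(early_decay_ratio(rep(1, length(t)), t), "undefined")
})

test_that("deterministic cohorts give the analytic ED pair", {
  pop <- population_spec(a_sd = 0, b_sd = 0, tau_sd = 0, noise_sd = 0,
                         mu_lambda = 0, n_subjects = 6, probe_frac = 1)
  pairs <- simulate_ed_distribution(0, pop, n_sims = 3, seed = 1)
  a <- 0.875; b <- 0.36; tau <- 40
  e50 <- b + (a - b) * mean_exp_window(tau, 1, 50)
  l75 <- b + (a - b) * mean_exp_window(tau, 251, 325)
  expected <- (a - e50) / (a - l75)
  expect_equal(pairs$ed_high, rep(expected, 3), tolerance = 1e-10)
  expect_equal(pairs$ed_low, rep(expected, 3), tolerance = 1e-10)
})

test_that("multivariate normal summary recovers known moments", {
  set.seed(8)
  n <- 1e4
  mu <- c(0.5, -0.1)
  A <- matrix(c(0.06, 0.02, 0, 0.03), 2)
  S <- A %*% t(A)
  z <- matrix(rnorm(2 * n), n) %*% t(A)
  pairs <- data.frame(ed_high = mu[1] + z[, 1], ed_low = mu[2] + z[, 2])
  fit <- fit_mvn(pairs)
  expect_equal(unname(fit$mean), mu, tolerance = 0.01)
  expect_equal(unname(fit$cov), S, tolerance = 0.05)
  # density integrates to ~1 over a wide grid
  g <- seq(-1, 2, length.out = 120)
  h <- g[2] - g[1]
  mass <- sum(exp(outer(g, g, Vectorize(function(x, y)
    fit$log_density(c(x, y)))))) * h^2
  expect_equal(mass, 1, tolerance = 0.01)
  # identical pairs: jitter keeps the density evaluable
  flat <- fit_mvn(data.frame(ed_high = rep(0.4, 12), ed_low = rep(0.2, 12)))
  expect_true(is.finite(flat$log_density(c(0.4, 0.2))))
  expect_error(fit_mvn(pairs[1:5, ]), "10 pairs")
})

test_that("exponential delay facts match the printed analytic values", {
  facts <- exp_delay_facts(90)
  expect_equal(round(100 * facts$fraction_above(50)), 57)
  expect_equal(round(100 * facts$fraction_below(10)), 11)
  expect_equal(facts$fraction_above(50), exp(-50 / 90), tolerance = 1e-12)
  expect_equal(facts$median, 90 * log(2))
  expect_equal(facts$median, 62.38, tolerance = 1e-3)
  # zero mean is a point mass at zero
  f0 <- exp_delay_facts(0)
  expect_equal(f0$fraction_below(5), 1)
  expect_equal(f0$fraction_above(5), 0)
  expect_equal(f0$median, 0)
  expect_error(exp_delay_facts(-1), ">= 0")
})

test_that("the posterior is a proper distribution with scale-free MAP", {
  grid <- 0:10
  # hand-built posterior machinery checks on a fake likelihood
  ll <- c(-2, -1, -5, -9, -12, -15, -18, -21, -24, -27, -30)
  w <- exp(ll - max(ll)); pr <- w / sum(w)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # rescaling the likelihood leaves the normalized posterior unchanged
  w2 <- exp((ll + 123) - max(ll + 123)); pr2 <- w2 / sum(w2)
  expect_equal(pr, pr2, tolerance = 1e-12)
  # real (small) run: normalization and reproducibility
  pop <- population_spec(n_subjects = 10)
  post <- posterior_mean_delay(c(0.5, 0.35), pop, grid = c(0, 30, 60, 90),
                               n_sims = 40, seed = 5)
  expect_equal(sum(post$prob), 1, tolerance = 1e-12)
  expect_true(post$map %in% c(0, 30, 60, 90))
  post2 <- posterior_mean_delay(c(0.5, 0.35), pop, grid = c(0, 30, 60, 90),
                                n_sims = 40, seed = 5)
  expect_identical(post$prob, post2$prob)
})

test_that("discrete HPD sets are the smallest covering sets", {
  grid <- 0:4
  prob <- c(0.55, 0.30, 0.10, 0.04, 0.01)
  h95 <- decaylab:::hpd_discrete(grid, prob, 0.95)
  expect_equal(unname(h95), c(0, 2))
  h80 <- decaylab:::hpd_discrete(grid, prob, 0.80)
  expect_equal(unname(h80), c(0, 1))
  h50 <- decaylab:::hpd_discrete(grid, prob, 0.50)
  expect_equal(unname(h50), c(0, 0))
})

test_that("mean simulated ed_low declines as the true mean delay grows", {
  pop <- population_spec(n_subjects = 40)
  means <- vapply(c(0, 30, 60, 90), function(mu) {
    mean(simulate_ed_distribution(mu, pop, n_sims = 60, seed = 100 + mu)$ed_low)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
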