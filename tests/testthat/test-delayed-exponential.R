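test_that("delayed exponential evaluates both branches correctly", {
  p <- delayed_exp_params(a = 0.85, b = 0.40, tau = 40, lam = 0)
  expect_equal(eval_delayed_exponential(p, 0), 0.85)       # t <= lam branch
  expect_equal(eval_delayed_exponential(p, 1e6), 0.40,
               tolerance = 1e-12)                          # asymptote
  # one time constant past onset: b + (a - b) * exp(-1)
  expect_equal(eval_delayed_exponential(p, 40), 0.40 + 0.45 * exp(-1),
               tolerance = 1e-12)
  expect_equal(eval_delayed_exponential(p, 40), 0.56554, tolerance = 2e-5)
  # vectorized
  expect_equal(eval_delayed_exponential(p, c(-5, 0)), c(0.85, 0.85))
})

test_that("invalid tau is rejected", {
  expect_error(delayed_exp_params(0.8, 0.4, 0, 0), "tau")
  expect_error(delayed_exp_params(0.8, 0.4, -3, 0), "tau")
})

test_that("model is continuous at the onset and monotone after it", {
  set.seed(41)
  for (i in 1:25) {
    p <- delayed_exp_params(a = runif(1, 0.4, 1.2), b = runif(1, -0.3, 0.39),
                            tau = runif(1, 2, 200), lam = runif(1, -50, 200))
    expect_lt(abs(eval_delayed_exponential(p, p$lam) -
                  eval_delayed_exponential(p, p$lam + 1e-9)), 1e-6)
    tt <- p$lam + sort(runif(10, 0.1, 300))
    expect_true(all(diff(eval_delayed_exponential(p, tt)) < 0))
  }
})

test_that("subject draws honor degenerate and stochastic population specs", {
  pop0 <- population_spec(a_sd = 0, b_sd = 0, tau_sd = 0, mu_lambda = 0)
  set.seed(1)
  p <- draw_subject(pop0)
  expect_equal(c(p$a, p$b, p$tau, p$lam), c(0.875, 0.360, 40, 0))
  # Expo(0) is a point mass: every draw is exactly zero
  set.seed(2)
  lams <- replicate(50, draw_subject(population_spec(mu_lambda = 0))$lam)
  expect_true(all(lams == 0))
  # law of large numbers on tau
  set.seed(3)
  taus <- replicate(1e4, draw_subject(population_spec())$tau)
  expect_lt(abs(mean(taus) - 40), 3 * 10 / sqrt(1e4))
  set.seed(4)
  lams <- replicate(1e4, draw_subject(population_spec(mu_lambda = 90))$lam)
  expect_lt(abs(mean(lams) - 90), 3 * 90 / sqrt(1e4))
})

test_that("noiseless subject simulation reproduces the model pointwise", {
  p <- delayed_exp_params(0.85, 0.40, 40, 10)
  s <- simulate_subject(p, noise_sd = 0, seed = 7)
  expect_equal(s$value, eval_delayed_exponential(p, s$t))
  expect_equal(nrow(s), 300 + 325)
  expect_equal(s$phase, ifelse(s$t <= 0, "training", "retention"))
  # zero-delay, zero-noise: all training trials at a
  s0 <- simulate_subject(delayed_exp_params(0.9, 0.2, 30, 0), 0, seed = 8)
  expect_true(all(s0$value[s0$t <= 0] == 0.9))
})

test_that("simulated white noise has the requested scale", {
  p <- delayed_exp_params(0.85, 0.40, 40, 0)
  s <- simulate_subject(p, noise_sd = 0.25, n_training = 5000,
                        n_retention = 5000, seed = 11)
  resid <- s$value - eval_delayed_exponential(p, s$t)
  expect_lt(abs(sd(resid) - 0.25) / 0.25, 0.02)
})

test_that("cohort simulation is deterministic and prefix-stable in seed", {
  pop <- population_spec(n_subjects = 8)
  c1 <- simulate_cohort(pop, seed = 42)
  c2 <- simulate_cohort(pop, seed = 42)
  expect_identical(c1$values, c2$values)
  expect_identical(c1$truth, c2$truth)
  expect_equal(dim(c1$values), c(8, 625))
  # enlarging the cohort leaves earlier subjects untouched
  pop_big <- population_spec(n_subjects = 12)
  c3 <- simulate_cohort(pop_big, seed = 42)
  expect_identical(c3$values[1:8, ], c1$values)
  # degenerate population: all subjects identical
  pop_d <- population_spec(a_sd = 0, b_sd = 0, tau_sd = 0, noise_sd = 0,
                           n_subjects = 4)
  cd <- simulate_cohort(pop_d, seed = 5)
  expect_true(all(apply(cd$values, 2, function(col) all(col == col[1]))))
})

test_that("white-noise retention residuals show no serial correlation", {
  p <- delayed_exp_params(0.85, 0.40, 40, 0)
  s <- simulate_subject(p, noise_sd = 0.25, n_training = 10,
                        n_retention = 1e4, seed = 13)
  resid <- s$value[s$t > 0] - eval_delayed_exponential(p, s$t[s$t > 0])
  prof <- partial_autocorrelation(resid, 10)
  expect_true(all(abs(prof$acf[-1]) < 3 / sqrt(1e4)))
  expect_true(all(abs(prof$pacf) < 3 / sqrt(1e4)))
})

test_that("tidy conversion and round-trip IO preserve a cohort", {
  pop <- population_spec(n_subjects = 3, n_training = 20, n_retention = 30)
  co <- simulate_cohort(pop, seed = 9)
  df <- as.data.frame(co)
  expect_equal(nrow(df), 3 * 50)
  expect_equal(unique(df$subject_id), c("s001", "s002", "s003"))
  expect_equal(df$value[df$subject_id == "s002"], co$values[2, ])
  path <- tempfile(fileext = ".csv")
  write_trial_series(df, path)
  back <- read_trial_series(path)
  expect_equal(back$value, df$value)
  expect_equal(back$t, df$t)
  expect_equal(back$phase, df$phase)
})

test_that("spec YAML round-trips", {
  path <- tempfile(fileext = ".yaml")
  pop <- population_spec(mu_lambda = 45, n_subjects = 20)
  write_spec_yaml(pop, path)
  pop2 <- read_spec_yaml(path)
  expect_equal(pop2, pop)
  ds <- drift_generative_spec(preset = "fitted")
  write_spec_yaml(ds, path)
  expect_equal(read_spec_yaml(path)$ar_mean, 0.92)
})
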