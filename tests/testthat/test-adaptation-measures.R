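test_that("curl field forces are proportional, orthogonal, and sign-symmetric", {
  ff <- force_field_spec(15)
  expect_equal(ideal_force_profile(0.5, ff), 7.5)
  expect_equal(ideal_force_profile(0, ff), 0)
  expect_equal(ideal_force_profile(0.5, force_field_spec(-15)), -7.5)
  # orthogonality F . v = 0 to machine precision for random velocities
  set.seed(1)
  v <- matrix(rnorm(200), ncol = 2)
  F <- curl_force(v, ff)
  expect_true(all(abs(rowSums(F * v)) < 1e-12))
})

test_that("adaptation coefficient is a through-origin gain", {
  set.seed(2)
  ideal <- 15 * abs(rnorm(100))
  expect_equal(adaptation_coefficient(ideal, ideal), 1)
  expect_equal(adaptation_coefficient(-0.5 * ideal, ideal), -0.5)
  # orthogonal (zero inner product) measured trace scores 0
  orth <- rnorm(100)
  orth <- orth - sum(orth * ideal) / sum(ideal^2) * ideal
  expect_equal(adaptation_coefficient(orth, ideal), 0, tolerance = 1e-12)
  expect_error(adaptation_coefficient(ideal, rep(0, 100)), "zero")
})

test_that("integrated lateral force is area-based and timing-insensitive", {
  tr <- synth_kinematics(adaptation_level = 1, duration = 0.4)
  expect_equal(integrated_lateral_force(tr$lateral_force, tr$ideal_force), 1)
  expect_equal(integrated_lateral_force(0.5 * tr$ideal_force, tr$ideal_force), 0.5)
  # a time-shifted equal-area profile keeps the integrated measure at 1
  lagged <- synth_kinematics(adaptation_level = 1, duration = 0.4,
                             force_lag = 0.05)
  expect_equal(integrated_lateral_force(lagged$lateral_force,
                                        lagged$ideal_force), 1,
               tolerance = 1e-6)
  # ... but drops the regression measure below 1
  expect_lt(adaptation_coefficient(lagged$lateral_force, lagged$ideal_force),
            0.95)
  # the two measures agree exactly on proportional profiles
  for (g in c(-1, 0.3, 0.5, 1)) {
    expect_equal(adaptation_coefficient(g * tr$ideal_force, tr$ideal_force),
                 integrated_lateral_force(g * tr$ideal_force, tr$ideal_force))
  }
})

test_that("synthetic kinematic round trips recover the adaptation level", {
  for (lev in c(1, 0.5, -0.3)) {
    tr <- synth_kinematics(adaptation_level = lev, duration = 0.35)
    expect_equal(adaptation_coefficient(tr$lateral_force, tr$ideal_force), lev)
    expect_equal(integrated_lateral_force(tr$lateral_force, tr$ideal_force), lev)
  }
})

test_that("control referencing removes a shared additive bias exactly", {
  set.seed(3)
  n_trials <- 50
  bias <- cumsum(rnorm(n_trials, 0, 0.05))  # slow shared drift
  signal <- matrix(rnorm(10 * n_trials), 10, n_trials)
  traces <- sweep(signal, 2, bias, `+`)
  expect_equal(control_reference(traces, bias), signal)
  expect_equal(control_reference(bias, bias), rep(0, n_trials))
  v <- rnorm(n_trials)
  expect_equal(control_reference(v, rep(0, n_trials)), v)
  expect_error(control_reference(traces, bias[-1]), "alignment")
})

test_that("overall decay follows the balanced formula", {
  s <- overall_decay(learning = c(1, -1), retention = c(0.5, -0.5),
                     group = c("P", "N"), n_boot = 50, seed = 1)
  expect_equal(s$overall_decay, 0.5)
  # retention equal to learning: no decay
  s0 <- overall_decay(learning = c(1, 0.9, -1, -0.8),
                      retention = c(1, 0.9, -1, -0.8),
                      group = c("P", "P", "N", "N"), n_boot = 50, seed = 1)
  expect_equal(s0$overall_decay, 0)
  expect_error(overall_decay(c(1, 1), c(0, 0), c("P", "N"), n_boot = 10),
               "separation")
})

test_that("overall decay is invariant to a shared constant offset", {
  set.seed(4)
  learning <- c(rnorm(10, 1, 0.1), rnorm(10, -1, 0.1))
  retention <- c(rnorm(10, 0.4, 0.1), rnorm(10, -0.4, 0.1))
  group <- rep(c("P", "N"), each = 10)
  s1 <- overall_decay(learning, retention, group, n_boot = 50, seed = 9)
  s2 <- overall_decay(learning + 5, retention + 5, group, n_boot = 50, seed = 9)
  expect_equal(s2$overall_decay, s1$overall_decay)
})

test_that("bootstrap SE matches the delta-method SE on normal values", {
  # learning fixed (huge separation), retention noisy: the statistic is
  # linear in the subgroup retention means, so its SE has a closed form
  set.seed(5)
  nP <- 40; nN <- 40
  sdr <- 0.3
  learning <- c(rep(1, nP), rep(-1, nN))
  retention <- c(rnorm(nP, 0.4, sdr), rnorm(nN, -0.4, sdr))
  group <- rep(c("P", "N"), c(nP, nN))
  s <- overall_decay(learning, retention, group, n_boot = 4000, seed = 6)
  # SE of (RP - RN)/2 with plug-in (1/n) subgroup variances
  vP <- var(retention[1:nP]) * (nP - 1) / nP^2
  vN <- var(retention[-(1:nP)]) * (nN - 1) / nN^2
  se_analytic <- sqrt(vP + vN) / 2
  expect_lt(abs(s$boot_se - se_analytic) / se_analytic, 0.15)
})

test_that("asymptote measures use the documented windows", {
  pop <- population_spec(n_subjects = 3, noise_sd = 0, a_sd = 0, b_sd = 0,
                         tau_sd = 0)
  co <- simulate_cohort(pop, seed = 1)
  m <- asymptote_measures(co)
  expect_equal(m$learning, rep(0.875, 3))
  p <- delayed_exp_params(0.875, 0.36, 40, 0)
  expected_ret <- mean(eval_delayed_exponential(p, 151:325))
  expect_equal(m$retention, rep(expected_ret, 3))
})

test_that("movement characteristics summarize direction, reward and shape", {
  # straight on-axis reaches: no curvature, no angular spread, rewarded
  trials <- lapply(1:5, function(i) synth_kinematics(angle = 0, duration = 0.2))
  mc <- movement_characteristics(trials)
  expect_equal(mc$directional_variability, 0)
  expect_equal(mc$curvature, 0)
  expect_equal(mc$p_reward, 1)  # crosses 10 cm at 200 ms, inside the window
  expect_lt(abs(mc$duration - 0.2), 0.025)
  # angled clamp trials miss the target center
  far <- movement_characteristics(
    lapply(c(8, -8), function(a) synth_kinematics(angle = a, duration = 0.2)))
  expect_equal(far$p_reward, 0)
  expect_gt(far$directional_variability, 5)
  # directional variability tracks the imposed angular spread
  set.seed(6)
  angs <- rnorm(60, 0, 2.6)
  mc2 <- movement_characteristics(
    lapply(angs, function(a) synth_kinematics(angle = a, duration = 0.2)))
  expect_lt(abs(mc2$directional_variability - sd(angs)), 0.1)
  expect_error(movement_characteristics(list()), "empty")
})
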