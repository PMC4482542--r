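test_that("the ternary error pattern follows clamp geometry", {
  crit <- rejection_criteria()
  expect_equal(binary_error_pattern(rep(0, 10), crit), rep(0L, 10))
  # 100 mm * sin(10 deg) = 17.4 mm, a clear rightward miss
  expect_equal(binary_error_pattern(10, crit), 1L)
  expect_equal(binary_error_pattern(-10, crit), -1L)
  # 100 mm * sin(3 deg) = 5.23 mm, inside any hit tolerance in play
  expect_equal(binary_error_pattern(3, crit), 0L)
  expect_equal(100 * sin(3 * pi / 180), 5.234, tolerance = 1e-3)
  # with the reward radius as threshold the boundary is asin(6/100) = 3.44 deg
  crit6 <- rejection_criteria(hit_lateral_max = 6)
  expect_equal(binary_error_pattern(c(3.43, 3.45), crit6), c(0L, 1L))
  # the default large-error threshold flips at asin(8/100) = 4.59 deg
  expect_equal(binary_error_pattern(c(4.58, 4.61), crit), c(0L, 1L))
})

test_that("rejection rules fire in the documented order", {
  crit <- rejection_criteria()
  # all-zero: no misses at all, so the gap rule rejects
  r <- passes_criteria(rep(0L, 50), crit)
  expect_false(r$pass); expect_equal(r$rule, "gap")
  # six consecutive +1: 5-trial smooth hits 1.0
  p <- rep(c(-1L, 1L), 25); p[10:15] <- 1L
  r <- passes_criteria(p, crit)
  expect_false(r$pass); expect_equal(r$rule, "smooth5")
  # strict alternation passes all three rules
  r <- passes_criteria(rep(c(1L, -1L), 30), crit)
  expect_true(r$pass); expect_true(is.na(r$rule))
  # a 26-trial miss-free stretch trips the gap rule without smoothing breaches
  p <- c(rep(c(1L, -1L), 10), rep(0L, 26), rep(c(1L, -1L), 10))
  r <- passes_criteria(p, crit)
  expect_false(r$pass); expect_equal(r$rule, "gap")
  expect_error(passes_criteria(rep(0L, 5), crit), "9 trials")
})

test_that("criteria are symmetric under sign flip", {
  crit <- rejection_criteria()
  set.seed(21)
  for (i in 1:200) {
    p <- sample(c(-1L, 0L, 1L), 60, replace = TRUE,
                prob = c(0.3, 0.4, 0.3))
    expect_identical(passes_criteria(p, crit)$pass,
                     passes_criteria(-p, crit)$pass)
  }
})

test_that("mirroring is an involution that preserves acceptance", {
  s <- generate_vec_sequence(length = 325, sd = 2.6, max_attempts = 2e6,
                             seed = 31)
  expect_true(s$accepted)
  expect_equal(length(s$angles), 325)
  m <- mirror_sequence(s)
  expect_equal(m$angles, -s$angles)
  expect_equal(m$pattern, -s$pattern)
  expect_equal(mirror_sequence(m)$angles, s$angles)
  # mirrored pattern matches recomputation from mirrored angles
  expect_equal(m$pattern, binary_error_pattern(m$angles, s$criteria))
  # acceptance of the mirror follows from criteria symmetry
  expect_true(passes_criteria(m$pattern, s$criteria)$pass)
  # sample sd near the target
  expect_lt(abs(sd(s$angles) - 2.6), 0.35)
})

test_that("sequence generation fails loudly when attempts run out", {
  err <- tryCatch(generate_vec_sequence(max_attempts = 10, seed = 1),
                  vec_no_sequence_found = function(e) e)
  expect_s3_class(err, "vec_no_sequence_found")
  expect_equal(err$attempts, 10)
})

test_that("linear sequence responses behave as a lagged linear system", {
  model <- linear_response_model(k_stiff = -0.03, k_learn = 0)
  expect_equal(sequence_response(c(1, 0, 0), model), c(-0.03, 0, 0))
  model2 <- linear_response_model(k_stiff = -0.03, k_learn = -0.01)
  ang <- c(2, -1, 0, 3)
  expect_equal(sequence_response(ang, model2),
               -0.03 * ang + -0.01 * c(0, 2, -1, 0))
  expect_equal(sequence_response(rep(0, 5), model2), rep(0, 5))
  # linearity: response to the mirror is the exact negative
  set.seed(5)
  ang <- rnorm(50, 0, 2.6)
  expect_equal(sequence_response(-ang, model2), -sequence_response(ang, model2))
})

test_that("mirror balancing cancels sequence responses exactly", {
  set.seed(6)
  ang <- rnorm(325, 0, 2.6)
  decay <- eval_delayed_exponential(delayed_exp_params(0.9, 0.3, 40, 0), 1:325)
  for (km in list(c(-0.03, -0.01), c(0.05, 0.02), c(-0.1, 0.3))) {
    model <- linear_response_model(km[1], km[2])
    r <- sequence_response(ang, model)
    r_m <- sequence_response(-ang, model)
    balanced <- ((decay + r) + (decay + r_m)) / 2
    expect_equal(balanced, decay)
  }
})

test_that("sequence-effect estimation and removal invert the corruption", {
  set.seed(7)
  ang <- rnorm(325, 0, 2.6)
  model <- linear_response_model()
  r <- sequence_response(ang, model)
  decay <- eval_delayed_exponential(delayed_exp_params(0.9, 0.3, 40, 0), 1:325)
  eff <- estimate_sequence_effect(decay + r, decay - r)
  expect_equal(eff, r)
  expect_equal(estimate_sequence_effect(decay, decay), rep(0, 325))
  expect_error(estimate_sequence_effect(1:5, 1:6), "length")
  # removal restores pure decay for a noiseless linear responder
  p <- delayed_exp_params(0.9, 0.3, 40, 0)
  s <- simulate_subject(p, noise_sd = 0, seed = 8)
  ret <- s$t >= 1
  s$value[ret] <- s$value[ret] + r
  fixed <- remove_sequence_effect(s, r, group = "1a")
  expect_equal(fixed$value[ret], eval_delayed_exponential(p, s$t[ret]))
  # group 1b gets the negated correction
  s2 <- simulate_subject(p, noise_sd = 0, seed = 8)
  s2$value[ret] <- s2$value[ret] - r
  fixed2 <- remove_sequence_effect(s2, r, group = "1b")
  expect_equal(fixed2$value[ret], eval_delayed_exponential(p, s2$t[ret]))
  expect_error(remove_sequence_effect(s, r, group = "2"), "group")
})

test_that("sequence-effect recovery works on noisy mirrored cohorts", {
  set.seed(9)
  ang <- rnorm(325, 0, 2.6)
  model <- linear_response_model()
  r <- sequence_response(ang, model)
  p <- delayed_exp_params(0.875, 0.36, 40, 0)
  decay <- eval_delayed_exponential(p, 1:325)
  n <- 20
  arm <- function(sign) {
    rowm <- replicate(n, decay + sign * r + rnorm(325, 0, 0.25))
    rowMeans(rowm)
  }
  eff <- estimate_sequence_effect(arm(1), arm(-1))
  expect_gt(cor(eff, r), 0.8)
})

test_that("trial-to-trial variance quantifies roughness", {
  expect_equal(trial_to_trial_variance(rep(3, 10)), 0)
  # alternating +c/-c: differences alternate +-2c, population variance 4c^2
  c0 <- 0.7
  x <- c(rep(c(c0, -c0), 20), c0)  # odd length so the differences sum to 0
  d <- diff(x)
  m <- length(d)
  expect_equal(trial_to_trial_variance(x) * (m - 1) / m, 4 * c0^2)
  # white noise: variance of differences ~ 2 sigma^2
  set.seed(10)
  w <- rnorm(2e4, 0, 0.3)
  expect_lt(abs(trial_to_trial_variance(w) - 2 * 0.09) / (2 * 0.09), 0.05)
  expect_error(trial_to_trial_variance(1), "2 trials")
  # removing a mirrored-pair sequence effect reduces roughness
  set.seed(11)
  ang <- rnorm(325, 0, 2.6)
  r <- sequence_response(ang, linear_response_model(-0.05, -0.03))
  decay <- eval_delayed_exponential(delayed_exp_params(0.9, 0.3, 40, 0), 1:325)
  noisy <- decay + r + rnorm(325, 0, 0.05)
  cleaned <- noisy - r
  expect_lt(trial_to_trial_variance(cleaned), trial_to_trial_variance(noisy))
})

test_that("vEC sequences round-trip through CSV with their sidecar", {
  s <- generate_vec_sequence(length = 60, sd = 2.6,
                             criteria = rejection_criteria(max_gap = 60),
                             max_attempts = 1e5, seed = 13)
  path <- tempfile(fileext = ".csv")
  write_vec_sequence(s, path)
  back <- read_vec_sequence(path)
  expect_equal(back$angles, s$angles, tolerance = 1e-12)
  expect_equal(back$pattern, s$pattern)
  expect_equal(back$attempts, s$attempts)
  expect_equal(back$sd_target, 2.6)
})
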