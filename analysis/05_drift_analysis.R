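#!/usr/bin/env Rscript
# Correlated noise (drift) in retention traces and its effect on
# individual onset-delay estimates.
#
# Simulates 60 zero-delay subjects from the drift generative model
# (D ~ N(0.56, 0.28^2), tau = 35.8, ARMA(1,1) retention noise) and a
# matched no-drift variant (independent retention noise, per-subject sd
# ~ N(0.23, 0.07^2)); characterizes the noise by ACF/PACF and ARMA fits;
# and fits unconstrained delayed exponentials to show how drift widens the
# delay-estimate distribution despite every subject decaying immediately.

library(decaylab)

seed <- 20260926L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

spec <- drift_generative_spec()
co_d <- simulate_drift_cohort(spec, n_subjects = 60, drift = TRUE, seed = seed)
co_n <- simulate_drift_cohort(spec, n_subjects = 60, drift = FALSE,
                              seed = seed + 1)

# Noise structure: per-subject ACF/PACF of demeaned retention residuals.
profile_of <- function(cohort, label) {
  resid <- demean_across_subjects(cohort$values, cohort$t, start_trial = 76)
  acfs <- t(apply(resid, 1, function(x) autocorrelation(x, 10)$acf))
  pacfs <- t(apply(resid, 1, function(x) partial_autocorrelation(x, 10)$pacf))
  data.frame(condition = label, lag = 0:10,
             acf = colMeans(acfs),
             pacf = c(NA, colMeans(pacfs)))
}
profiles <- rbind(profile_of(co_d, "drift"), profile_of(co_n, "no_drift"))
write.csv(profiles, file.path(out_dir, "drift_correlation_profiles.csv"),
          row.names = FALSE)
cat("mean ACF (lags 1-3), drift:   ",
    round(profiles$acf[profiles$condition == "drift"][2:4], 3), "\n")
cat("mean ACF (lags 1-3), no drift:",
    round(profiles$acf[profiles$condition == "no_drift"][2:4], 3), "\n")

# Population descriptors and their comparison.
dd <- drift_descriptors(co_d)
dn <- drift_descriptors(co_n)
cmp <- population_comparison(dd, dn)
write.csv(cmp$summary, file.path(out_dir, "drift_descriptor_summary.csv"),
          row.names = FALSE)
cat(sprintf("mean fitted AR (drift cohort): %.2f; PAC1 %.2f vs %.2f (no drift)\n",
            mean(dd$ar), mean(dd$pac1), mean(dn$pac1)))

# Delay-estimate dispersion: unconstrained fits over trials -150..325.
fit_d <- fit_cohort(co_d)
fit_n <- fit_cohort(co_n)
write.csv(rbind(cbind(condition = "drift", fit_d$fits),
                cbind(condition = "no_drift", fit_n$fits)),
          file.path(out_dir, "drift_delay_fits.csv"), row.names = FALSE)
cat(sprintf("delay IQR: %.1f trials with drift vs %.1f without\n",
            fit_d$summary$iqr_lam, fit_n$summary$iqr_lam))
cat("Drift of this magnitude alone broadens the spread of best-fit onset\n")
cat("delays by several-fold even though every simulated subject decays\n")
cat("immediately - large individual delay estimates are not evidence of\n")
cat("truly delayed decay.\n")
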