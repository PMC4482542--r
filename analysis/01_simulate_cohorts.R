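#!/usr/bin/env Rscript
# Reference cohort simulations for the group-level decay-onset analysis.
#
# Simulates 40-subject cohorts whose subjects hold a pre-decay asymptote
# a ~ N(0.875, 0.100^2) through an exponentially distributed onset delay and
# then decay with tau ~ N(40, 10^2) toward b ~ N(0.360, 0.200^2), with white
# trial noise (sd 0.25) and training-phase adaptation measurable only on the
# 20% error-clamp probe trials. Writes one example cohort per condition and
# the median-divided subgroup mean traces that the early-decay-ratio
# statistic is computed from.

library(decaylab)

seed <- 20260926L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

for (mu in c(0, 90)) {
  pop <- population_spec(mu_lambda = mu, n_subjects = 40)
  cohort <- simulate_cohort(pop, seed = seed + mu)
  # keep the archived example compact: three subjects' full series
  example <- as.data.frame(cohort)
  example <- example[example$subject_id %in% c("s001", "s002", "s003"), ]
  write_trial_series(example,
                     file.path(out_dir, sprintf("cohort_mu%02d_examples.csv", mu)))
  split <- median_divide(cohort)
  pair <- cohort_ed_pair(cohort, split)
  traces <- data.frame(
    t = cohort$t,
    mean_high = colMeans(cohort$values[split$high, ]),
    mean_low = colMeans(cohort$values[split$low, ]))
  write.csv(traces,
            file.path(out_dir, sprintf("subgroup_traces_mu%02d.csv", mu)),
            row.names = FALSE)
  cat(sprintf(
    "mu_lambda = %2d: ED high %.3f, ED low %.3f (one 40-subject cohort)\n",
    mu, pair[["ed_high"]], pair[["ed_low"]]))
}

cat("\nInterpretation: with immediate decay (mu = 0) both subgroups decay\n")
cat("inside the first 50 retention trials (both ratios well above zero);\n")
cat("with mean delay 90 the low-decay subgroup shows essentially no early\n")
cat("decay and its ratio sits near or below zero via the noise-selection\n")
cat("bias of the median division.\n")
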