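#!/usr/bin/env Rscript
# Constraint-induced bias in decay-onset estimation.
#
# Simulates zero-delay subjects (a = 0.85, b = 0.40, tau = 40, white noise
# sd 0.2) and fits each trace twice over trials -150..325: onset delay free
# within the data window versus constrained non-negative. The free
# estimates form a bell centered at zero; the constraint folds the negative
# half onto exactly zero, leaving an exclusively non-negative, positively
# biased distribution. Set DECAYLAB_BIAS_N to override the subject count
# (default 10000; ~20 min on one core).

library(decaylab)

n <- as.integer(Sys.getenv("DECAYLAB_BIAS_N", "10000"))
seed <- 20260926L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

bx <- bias_experiment(n = n, seed = seed)
print(bx)

write.csv(data.frame(subject = seq_len(n),
                     lam_free = bx$unconstrained,
                     lam_constrained = bx$constrained),
          file.path(out_dir, "bias_experiment_delays.csv"), row.names = FALSE)

s <- bx$summary
write.csv(data.frame(statistic = names(s), value = as.numeric(unlist(s))),
          file.path(out_dir, "bias_experiment_summary.csv"), row.names = FALSE)

brk <- seq(-105, 330, by = 5)
h_free <- hist(bx$unconstrained, breaks = brk, plot = FALSE)$counts
h_cons <- hist(bx$constrained, breaks = brk, plot = FALSE)$counts
write.csv(data.frame(bin_lo = head(brk, -1), bin_hi = brk[-1],
                     free = h_free, constrained = h_cons),
          file.path(out_dir, "bias_experiment_histograms.csv"),
          row.names = FALSE)

cat(sprintf(
  "\nThe constrained distribution piles %.0f%% of subjects at exactly zero,\n",
  100 * s$frac_constrained_at_zero))
cat("mirroring the free fits' negative half — a shape easily mistaken for\n")
cat("an exponential spread of true delays.\n")
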