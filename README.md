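# decaylab

Simulation and inference tools for studying the decay of motor adaptation
after error feedback is withheld.

## The problem

After people adapt their reaching movements to a velocity-dependent force
field, clamping subsequent movements to straight paths (error-clamp trials)
removes error feedback — and the learned compensation regresses toward
baseline. Whether that regression starts *immediately* (intrinsic
trial-by-trial decay) or only *after the sensorimotor system detects a
context change* (context-dependent decay) is distinguishable by the decay
onset delay, and by whether masking the context change with
variable-direction error clamps (vEC) postpones decay. decaylab provides,
as tested R code, the machinery needed to ask that question of
trial-by-trial adaptation data and to calibrate the analyses on synthetic
cohorts: who is it for — computational motor-control researchers who need
the full pipeline (generators, estimators, inference) rather than a single
fit function.

## The model and the estimators

A subject's adaptation trace around the training-to-retention transition is
a delayed exponential (trial `t` relative to retention onset):

    f(t) = a                                  for t <= lambda
    f(t) = (a - b) exp(-(t - lambda)/tau) + b for t >  lambda

The package implements:

* **Cohort simulation** — per-subject `(a, b, tau)` from population
  normals, exponentially distributed onset delays `lambda ~ Expo(mu)`,
  white trial noise, optional ARMA(1,1) drift in retention, and the
  experiment's measurement model (training adaptation observable only on
  the 20% error-clamp probe trials).
* **vEC sequence generation** — rejection sampling of 325-trial clamp
  direction sequences `N(0, 2.6^2)` degrees against smoothed-error-pattern
  and miss-gap criteria; mirroring and mirror-balanced removal of
  sequence-locked responses.
* **Force-based adaptation measures** — adaptation coefficient
  (through-origin regression on the ideal curl-field compensation),
  integrated lateral force (timing-insensitive), control referencing,
  balanced overall decay with bootstrap SE.
* **Delayed-exponential fitting** — bounded multi-start nonlinear least
  squares with the onset either free within the data window or constrained
  non-negative, plus the demonstration that the constraint biases
  zero-delay estimates upward.
* **Group-level inference** — median division by early decay, the early
  decay ratio `(L - E)/(L - A)`, simulation-based likelihoods of the
  subgroup ratio pair, and a discrete Bayesian posterior over the
  population mean onset delay (grid 0–90 trials, uniform prior, MAP and
  HPD intervals).
* **Drift analysis** — full-overlap ACF, regression-definition PACF,
  conditional-least-squares ARMA(1,1) fits, and drift vs no-drift
  population comparisons.

## Worked example

Simulate a 40-subject cohort whose mean onset delay is 90 trials, median
divide it, and compute the early-decay-ratio pair; then ask the posterior
what the observed pair from a zero-delay cohort implies:

```r
library(decaylab)

pop <- population_spec(mu_lambda = 90, n_subjects = 40)
cohort <- simulate_cohort(pop, seed = 1)
cohort_ed_pair(cohort)
#>     ed_high      ed_low
#>  0.25883051 -0.09789957

# observed pair from an immediate-decay cohort
obs <- cohort_ed_pair(simulate_cohort(population_spec(n_subjects = 40),
                                      seed = 2))
obs
#>   ed_high    ed_low
#> 0.4963    0.3641
post <- posterior_mean_delay(obs, population_spec(n_subjects = 40),
                             grid = 0:90, n_sims = 200, seed = 3)
post
#> Posterior over mean decay-onset delay (grid 0..90, 200 sims/point)
#>   observed ED pair: high 0.50, low 0.36
#>   MAP = 0 trials; 95% HPD [0, 3]; 99% HPD [0, 5]
```

The delayed-delay cohort shows the diagnostic signature: its low-decay
subgroup keeps essentially full adaptation through the first 50 retention
trials (ratio near or below zero — slightly negative because median
division preferentially sorts lucky-noise subjects into that subgroup),
while the high-decay subgroup's ratio stays moderate. Feeding the posterior
an immediate-decay cohort's pair concentrates the posterior at a mean delay
of zero trials.

The `analysis/` directory holds the narrative reproduction drivers
(`01_simulate_cohorts.R` … `05_drift_analysis.R`); each writes its tables
under `results/`.

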