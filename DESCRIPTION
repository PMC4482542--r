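Package: decaylab
Title: Simulation and Inference for the Decay of Motor Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying trial-by-trial decay of force-field motor
    adaptation after error feedback is withheld. Simulates per-subject
    adaptation traces with delayed exponential decay, white measurement
    noise and ARMA(1,1) drift; generates statistically constrained
    variable-error-clamp direction sequences by rejection sampling;
    computes force-based adaptation measures (adaptation coefficient and
    integrated lateral force) and balanced decay summaries; fits delayed
    exponential onset models with and without a non-negativity constraint
    on the onset delay, demonstrating constraint-induced bias; and carries
    out a simulation-based Bayesian inference of the population mean decay
    onset delay from early-decay-ratio statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
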