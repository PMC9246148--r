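Package: bndd
Title: Bayesian Nonparametric Discontinuity Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian-process-based causal inference for quasi-experimental
    designs with a known threshold. Compares a continuous model against a
    discontinuous model at the threshold via BIC-approximated Bayes factors,
    and reports a model-averaged (spike-and-slab) effect-size distribution.
    Supports sharp regression discontinuity, interrupted time series with a
    spectral mixture covariance function initialized from the Lomb-Scargle
    periodogram, and two-dimensional geographic boundary designs, together
    with seeded simulation generators and benchmark runners (two-stage GP
    test and an ARMA extrapolation baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
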