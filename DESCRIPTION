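Package: kosens
Title: External Potassium Sensitivity Analysis for KCNQ1-Type Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the inhibition of voltage-gated potassium
    channels by external K+. Implements Goldman-Hodgkin-Katz (GHK) flux and
    current-ratio models, Hill dose-response fitting with GHK driving-force
    correction, Boltzmann-with-offset activation fits, multi-exponential
    tail-current fitting with a fractional fast-inactivation statistic,
    single-channel all-point histogram and conductance analysis, and
    selectivity-filter ion-permeation analysis of molecular dynamics
    trajectories (substate classification, permeation-event detection,
    conduction-mode assignment). Seeded synthetic-data generators with
    ground-truth logs are provided for every input class so that each
    analysis can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
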