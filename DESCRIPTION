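Package: cfsim
Title: Continuous Flash Suppression Stimuli, Retinotopic Adaptation
    Simulation, and Bayesian Threshold Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying interocular suppression of moving stimuli
    with continuous flash suppression (CFS) and moving Mondrian masks (MMM).
    Generates seeded mask and target frame sequences, quantifies
    retinotopically specific neural adaptation via odd-symmetric Gabor
    filtering, five-way response classification and exponential
    decay/recovery dynamics, runs accelerated one-up-two-down staircases
    against simulated observers, and analyses normalized contrast thresholds
    with hierarchical robust-t repeated-measures models (via JAGS) and
    default-prior (JZS) ANOVA Bayes factors. Includes a ground-truthed
    synthetic-data generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
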