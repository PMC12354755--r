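Package: qpupil
Title: Q-Learning Models, Hierarchical Bayesian Inference and Pupillometry
    for Noradrenergic Pharmacology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing probabilistic reinforcement learning tasks
    in within-subject drug crossover designs. Implements the two-parameter
    Q-learning model (Rescorla-Wagner delta rule with softmax choice),
    non-centred hierarchical Bayesian estimation with drug-offset
    parameters via Hamiltonian Monte Carlo, posterior summaries
    (probability of direction, highest density intervals, region of
    practical equivalence), optimal-strategy grid simulation and
    joint-parameter-space distance analysis, pupillometry preprocessing
    (blink interpolation, Butterworth filtering, baseline workflow,
    temporal derivative) with cluster-mass permutation testing, and
    plausible-values correlation between latent parameters and observed
    covariates. Ships a synthetic-data module that generates task
    schedules, simulated cohorts with known hierarchical ground truth and
    synthetic pupil recordings, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
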