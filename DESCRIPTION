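Package: revlearn
Title: Feature-Based Reversal Learning: Task Simulation, Learning Models,
    Model Fitting and Behavioral Statistics
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing feature-based reversal learning behavior of
    the kind studied in primate attention and pharmacology experiments. The
    package provides a task simulator with un-cued color-reward reversals and
    a performance-triggered block-advance rule; eight trial-by-trial learning
    models (feature-value reinforcement learning with optional value decay
    and asymmetric learning rates, a Bayesian ideal-observer integrator, and
    hybrid Bayesian feature-weighting models with decay, dual learning rates,
    or choice-history perseveration); maximum-likelihood model fitting with
    multi-start simplex/quasi-Newton optimization, block-level 80/20
    cross-validation and AIC model comparison; state-space (Smith-Brown)
    estimation of trial-wise probability of rewarded choice and learning
    trials; and permutation statistics with pooled-null familywise
    correction for trial-aligned condition differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
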