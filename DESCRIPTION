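Package: rlddm
Title: Reinforcement Learning Drift Diffusion Modelling of Reward and Loss Avoidance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling probabilistic reward, neutral and loss avoidance
    instrumental learning with reinforcement learning drift diffusion models
    (RLDDM). Implements the Wiener first passage time likelihood with
    trial-varying drift rate and collapsing/expanding boundary variants,
    two-level hierarchical Bayesian estimation with rank-normalized split R-hat
    and tail effective sample size convergence diagnostics, k-fold
    cross-validated ELPD model comparison, parameter recovery and posterior
    predictive checking, trial-wise value and prediction error signal
    derivation with control-group detrending, group statistics and severity
    correlations, and export of event tables with parametric modulators. A
    synthetic task and cohort generator emulates the three-condition
    (reward/neutral/loss) probabilistic learning task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
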