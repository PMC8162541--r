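Package: ddmlong
Title: Longitudinal Stability and Change in Diffusion Model Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal stability and change in the core
    parameters of the Wiener diffusion model for two-choice response times.
    Provides the first-passage-time density and a trial simulator with dual
    non-decision times (correct responses and corrected error responses), a
    synthetic generator for longitudinal Implicit Association Test cohorts
    with known person-level growth trajectories, pre-fit trial and
    participant exclusion rules, per-occasion hierarchical Bayesian
    estimation with effect-coded condition structure, rank-normalized
    convergence diagnostics and posterior predictive checks, and four
    stability analyses on person-level posterior medians: Bayesian
    rank-order correlations, mean-level comparison via highest density
    intervals, Bayesian latent growth curve models with free slope
    loadings, and within-person profile (q) correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
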