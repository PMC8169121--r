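Package: sniffsearch
Title: Sniff-Synchronized Behavioral Motif Analysis for Olfactory Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for freely-moving rodent olfactory search
    behavior. Segments three-point pose trajectories into movement motifs
    with a Bayesian auto-regressive hidden Markov model (conjugate Gibbs
    sampling with matrix-normal-inverse-Wishart priors), detects and
    filters sniff cycles from intranasal thermistor traces, quantifies
    sniff-locked kinematic rhythms, maps investigation and approach
    occupancy across the arena, decodes trial labels from motif transition
    statistics with a shrinkage linear discriminant, and maps odor-plume
    discriminability with ROC analysis. Ships a synthetic-session
    generator with known ground truth so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
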