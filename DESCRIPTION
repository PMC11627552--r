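Package: msburst
Title: Transcriptional Bursting Analysis of MS2 Live-Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for transcriptional bursting in
    early fly embryos imaged with the MS2/MCP system. Implements a two-sister
    promoter (three-state) telegraph model with Gillespie simulation and an
    elongation-convolution fluorescence renderer; a compound-state hidden
    Markov model (cpHMM) with convolved Gaussian emissions fitted by
    Baum-Welch EM, with aggregation of the fitted three-state chain to
    effective two-state burst parameters (k_on, k_off, r); a synthetic embryo
    generator emulating genotype-specific even-skipped stripe patterns;
    stripe assignment by weighted k-means or manual anterior-posterior
    boundaries with endogenous/ectopic labeling; fluorescence binning with
    per-bin inference, bootstrap uncertainties and bursting-strategy
    comparison; and pseudo-stripe registration with kymograph construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    Matrix
Config/testthat/edition: 3
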