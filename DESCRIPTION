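Package: cinesync
Title: Group-Synchronized Responses and Content Bias in Naturalistic Movie fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse-correlation analysis of naturalistic movie fMRI:
    detection of group-synchronized BOLD time points via bootstrap confidence
    intervals for the group median against a family-wise null of phase-randomized
    maxima, mapping of synchronized time points to lagged labeled movie bins,
    permutation tests for content bias (e.g. drug-cue bias) between groups and
    across sessions with Benjamini-Hochberg correction, single-component shared
    response model alignment per region of interest, and leave-one-out
    inter-subject correlation with behavioral (craving) correlates. Includes a
    synthetic study generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: FFTW3
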