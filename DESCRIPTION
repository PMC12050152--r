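Package: mfcoupling
Title: Morphology-Function Coupling Analysis for Parcellated Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs subject-level morphological similarity networks from
    regional gray-matter value distributions using kernel density estimation
    with automatic (diffusion) bandwidth selection and a symmetric
    Kullback-Leibler divergence similarity, builds functional connectivity
    networks from regional time series, quantifies regional and global
    morphology-function coupling by column-wise Spearman correlation, and
    provides the accompanying group-level statistical battery: empirical-Bayes
    site harmonization, covariate residualization, Mann-Whitney tests with
    false discovery rate control, partial correlation with symptom scores, and
    spatial (spin) permutation nulls. Includes a synthetic cohort generator
    with analytically known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
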