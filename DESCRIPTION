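Package: inocula
Title: Colonization Success Analysis for Fungal Inoculation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing log-inoculation field experiments on
    wood-inhabiting fungi. Builds the experimental site/log/species layout,
    simulates resident fungal communities, spike-in metabarcoding read
    tables and binary colonization outcomes from a known probit process,
    derives the response and abiotic/biotic predictor sets (richness,
    model-based ordination scores, common-species occurrences and
    abundances, spike-calibrated DNA amount), fits Bayesian probit
    regressions with a site random intercept and optional spike-and-slab
    variable selection via a Gibbs sampler, and compares candidate models
    by leave-one-out cross-validated AUC and variance partitioning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
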