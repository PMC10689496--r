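Package: urheimat
Title: Dating Language Families and Locating Their Homelands from Cognate,
    Ecological and Genetic Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for dating a small language family and
    locating its homeland. Implements tip-dated Bayesian phylogenetic
    inference on binary cognate matrices (binary CTMC, binary covarion and
    stochastic Dollo likelihoods, gamma rate heterogeneity, per-concept
    rates, strict and uncorrelated-lognormal clocks, fossilized birth-death
    tree prior, tip and node calibrations), nested-sampling marginal
    likelihoods and Bayes-factor model ranking, maximum-entropy habitat
    suitability modelling with maxSSS binarization and multi-taxon
    co-occurrence mapping, multinomial biome-climate classification with
    society-biome association tables, and principal-component projection of
    high-missingness ancient genotypes. A synthetic-data generator emulates
    every input (dated trees, cognate matrices, climate fields, taxon
    occurrences, dated pollen and archaeological sites, genotype panels) so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
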