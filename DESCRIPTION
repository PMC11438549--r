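Package: peptideml
Title: Automated Development of Peptide Bioactivity Predictors with
    Homology-Aware Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for building binary peptide bioactivity
    predictors: bioactivity-aware negative sampling from a tagged peptide
    database with length-histogram matching, homology-based train/test
    partitioning via connected components on a sequence-identity graph
    (with a provable zero-leakage guarantee), pluggable mean-pooled peptide
    representations (one-hot baseline, deterministic mock language-model
    embedder, precomputed-embedding import), hyperparameter-optimized
    ensembles of KNN, gradient boosting and random forest classifiers
    scored by cross-validated Matthews correlation coefficient, and
    reproducible evaluation reports. Includes a synthetic peptide-family
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    FNN,
    generics,
    graphics,
    ggplot2,
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
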