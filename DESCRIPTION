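Package: affinet
Title: Ensemble Neural-Network Scoring Functions for Protein-Ligand
    Binding Affinity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring functions for protein-ligand binding affinity built
    from ensembles of single-hidden-layer feed-forward neural networks:
    bagged ensembles with bootstrap resampling and random feature
    subspaces (BgN-Score), stage-wise boosted ensembles fit to shrunken
    residuals (BsN-Score), and a single-network baseline (SNN-Score).
    Includes weight-decay regularised network training, out-of-bag and
    k-fold validation, scoring-power metrics (Pearson and Spearman
    correlation, standard deviation of errors about a fitted line, and
    RMSE), feature-block combination and dataset-splitting utilities for
    PDBbind-style benchmarks, a seeded generator of synthetic feature
    tables with known ground truth, and an intermolecular element-pair
    contact descriptor extractor for PDB/SDF structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    ChemmineR,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
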