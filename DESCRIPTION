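Package: gc2mat
Title: Germ-Cell-to-Maternal Transition Transcriptomics and Chromatin Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the germ-cell-to-maternal transition in the
    Drosophila ovary. Implements a negative-binomial count-model engine
    (median-of-ratios and TMM normalization, empirical-Bayes dispersion
    estimation, GLM fitting, Wald and likelihood-ratio contrast tests,
    Benjamini-Hochberg adjustment), differential expression with low-count
    filtering and fold-change classification, differential translational
    efficiency from polysome profiling via an interaction contrast,
    multi-set overlap statistics with empirical randomization and
    hypergeometric tests, stage-signature negative-binomial regression of
    TPM profiles, TOP-motif classification of 5' termini from CAGE
    transcription start sites, differential chromatin-mark quantification
    over promoters, gene bodies and TAD meta-regions, and synthetic-data
    generators with recorded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
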