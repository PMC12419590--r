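Package: stmir
Title: Spatially Resolved miRNA Activity Inference from mRNA Expression
Version: 0.1.0
Authors@R:
    person("STmiR", "Developers", email = "stmir-dev@example.org",
           role = c("aut", "cre"))
Description: Learns per-miRNA regressors from integrated paired bulk
    mRNA/miRNA cohorts and transfers them to spatial transcriptomics
    spots to produce spot-level predicted miRNA activity. Two bulk
    cohorts are harmonized with a rank-based inverse-normal pipeline
    that removes monotone batch effects; gradient-boosted regression
    trees (implemented natively) predict each miRNA from mRNA features;
    Visium-style spot matrices are quality-controlled, normalized and
    encoded for the trained model; spot activity is attributed to
    dominant cell types from an external deconvolution, and downstream
    differential-activity, miRNA-target correlation and gene-set
    enrichment statistics are provided, together with a seeded
    synthetic-data generator and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
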