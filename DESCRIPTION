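Package: velokin
Title: Stochastic Kinetic Inference and RNA Velocity from Metabolically
    Labeled Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers absolute RNA kinetic parameters (transcription,
    splicing and degradation rates, and transcriptional off-state
    probability) and time-resolved RNA velocity from metabolic-labeling
    single-cell RNA-seq count data. Measured counts are modeled with
    cell-specific Poisson-family distributions derived from chemical
    master equations of transcription, splicing, degradation and
    promoter switching combined with binomial capture noise. Provides a
    modified chi-square goodness-of-fit test for heterogeneous
    cell-specific distributions, maximum-likelihood estimators for
    one-shot and multi-duration pulse designs, kNN-based cell-specific
    parameter post-processing, total and spliced RNA velocity, velocity
    evaluation metrics, and Gillespie simulators of the labeling
    process for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, RNASeq, GeneExpression,
    StatisticalMethod, Software
RoxygenNote: 7.3.3
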