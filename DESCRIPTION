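Package: methylforge
Title: Genome-Wide Methylation Array Analysis for Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for Illumina 450k-style DNA
    methylation array data applied to tumor/normal cohorts: probe- and
    sample-level quality control, beta and M-value transforms, quantile
    normalization, cellularity-aware differential methylation with
    empirical-Bayes moderated statistics, bump-hunted differentially
    methylated regions with permutation family-wise error control, copy
    number inference from total signal intensities via recursive binary
    segmentation, and construction of a minimal CpG logistic classifier by
    ROC filtering, redundancy pruning and L1-regularized logistic
    regression. Includes a synthetic cohort generator with known ground
    truth (cellularity-diluted hypermethylation, regional bumps, copy
    number segments) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    mclust,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmnet,
    pROC,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
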