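Package: txdrift
Title: Transcriptional Drift and Fold-Change Analysis of Replicate RPKM Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-cohort, multi-tissue bulk RNA-seq
    expression matrices reported in RPKM units. Implements fold-change
    classification of age- and treatment-responsive genes against symmetric
    fold cutoffs, transcriptional drift relative to a young reference cohort
    with a permutation test for drift-variance differences, per-gene variance
    Z scores (coefficient of variation) and variance-change classification,
    hypergeometric gene-set over-representation, PCA quality control, and a
    synthetic replicate-RPKM generator with planted fold-change, restoration
    and drift structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
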