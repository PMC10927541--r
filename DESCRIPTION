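Package: scstructr
Title: Single-Cell RNA Structure Probing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-cell chemical RNA structure probing
    (mutational profiling) data: per-cell mutation rates and
    treated-minus-control SHAPE reactivities, cell quality control,
    pseudobulk aggregation, gene-level (2-8%) and quantile normalization,
    window-level structural heterogeneity by adjusted R-squared of a
    per-cell mutant-versus-depth linear fit, gene-level heterogeneity by
    cosine-distance dispersion against the pseudobulk, quantile
    classification, metagene enrichment, dynamic-time-warping k-means of
    heterogeneity trajectories, ROC/AUC benchmarking of reactivities
    against reference secondary structures, hypergeometric feature/RBP
    enrichment with Bonferroni correction, expression-stratified
    reactivity comparisons, and a fully seeded synthetic-data simulator
    with ground-truth heterogeneity labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
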