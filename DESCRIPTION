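Package: metaboRBG
Title: Recall-by-Genotype Untargeted Metabolomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control, normalization and dual-track genotype association
    analysis for untargeted UHPLC-MS metabolomics data from recall-by-genotype
    studies. Implements pooled-QC feature filtering (relative standard deviation
    and detection rate), sample filtering (missingness and total peak area),
    within-class missingness filtering, probabilistic quotient normalization,
    rank-based inverse-normal transformation, per-feature genotype association
    via linear and mixed models with Benjamini-Hochberg false discovery rate
    control, a presence/absence Fisher's exact test track for
    missing-not-at-random features, annotation deduplication, lipid-class
    summaries, Ward-clustered heatmaps and cohort characteristic tables. A
    seeded synthetic study generator emulates matched carrier:control designs
    across two cohorts with repeated measures, four assay datasets, per-sample
    dilution, technical noise and limit-of-detection censoring, and carries
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    pheatmap,
    ggplot2,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
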