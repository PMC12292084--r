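Package: oncostage
Title: Stage-Resolved Single-Cell Tumor Progression Analysis
Version: 0.1.0
Authors@R: person("Maintainer", "Oncostage", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for stage-resolved analysis of tumor
    single-cell RNA-seq data: expression-derived copy-number scoring and
    malignant-cell classification by windowed genomic signal, cluster
    purity/entropy stage-homogeneity metrics, Wilcoxon stage-marker
    extraction, consensus transcription-factor regulatory networks with
    recovery-curve regulon activity and Jensen-Shannon stage specificity,
    marker-based bulk-cohort stratification with Kaplan-Meier/log-rank
    survival comparison, and permutation-tested ligand-receptor
    communication differences between conditions. Ships a synthetic-data
    generator with full ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
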