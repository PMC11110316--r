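Package: semimeth
Title: Semimethylation Landscape, Methylation Variability, and
    Age-Standardized Telomere Length for Lymphoma Methylome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for methylation-array beta values and qPCR
    telomere measurements in large B-cell lymphoma cohorts. Partitions CpGs
    into hypo-, semi- and hypermethylated classes per sample and per CpG,
    computes the kernel-density Methylation Variability Score against a
    normal B-cell baseline, classifies samples by CpG island methylator
    phenotype, selects differentially methylated CpGs and enrichment-filtered
    hypermethylated CpG islands, converts qPCR cycle thresholds to relative
    telomere length with double-LOESS age standardization against a control
    cohort, and stratifies groups for Kaplan-Meier and Cox proportional
    hazards survival analysis. Includes seeded generators for synthetic beta
    matrices, qPCR plates, control cohorts and clinical outcome sheets so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
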