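Package: scnadriver
Title: Integration of Somatic Copy Number Alterations with Tumor Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying copy-number-driven genes in
    paired tumor/normal cohorts. Maps segmented DNA copy number onto gene
    annotations, derives deregulated-expression (DE) and somatic copy number
    alteration (SCNA) matrices normalized against non-tumor tissue, screens
    genes with a permutation t-test plus fold-change and Pearson-correlation
    gates, profiles gain/loss frequency landscapes along the genome, predicts
    molecular subclasses by Nearest Template Prediction with resampling-based
    false discovery control, and stratifies overall survival with Kaplan-Meier,
    log-rank and univariate Cox analyses. A synthetic-cohort generator with
    planted arm-level events, dosage-coupled expression, survival effects and
    subclass signatures makes every stage testable without access to
    controlled patient data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    grDevices,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
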