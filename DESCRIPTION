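Package: mfhet
Title: Genomic Inter-Lesion Heterogeneity Analysis for Multifocal Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-lesion tumour sequencing of multifocal
    breast cancer: cross-platform confirmation of somatic mutations with
    allele-fraction thresholds and a within-patient rescue rule, rule-based
    oncogenicity classification of unique variants, patient-level heterogeneity
    grouping (homogeneous, intermediate, heterogeneous) from per-sample presence
    matrices, private-versus-common comparison of mutations, rearrangements and
    segmented absolute copy-number profiles including a minimum-event inter-lesion
    copy-number distance, cohort-level statistics, and a synthetic-cohort
    generator with recorded ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    pROC,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
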