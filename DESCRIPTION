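Package: recurseq
Title: Somatic Filtering, Copy-Number and Recurrence-Biomarker Analysis for
    Tumor/Normal Sequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementation of a tumor/normal sequencing analysis
    pipeline for postoperative recurrence biomarkers in stage II/III
    colorectal cancer: a somatic-mutation discard cascade (depth, variant
    allele frequency, germline evidence, strand support, population-database
    membership), a GC-adjusted logR-ratio copy-number track with 1-Mb
    moving-window median smoothing and a simplified permutation test for
    recurrent gains and losses, a closed-form allele-specific LRR/BAF
    decomposition, biallelic two-hit tumor-suppressor inactivation
    classification integrating point mutations, loss of heterozygosity and
    structural variations, marker-gene predictive-value evaluation
    (sensitivity, specificity, PPV, NPV), Kaplan-Meier / log-rank / Cox
    proportional-hazards survival comparison, and shared-mutation clonal
    origin inference for synchronous and metachronous tumor pairs. A
    synthetic-cohort generator with known truth makes every step testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
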