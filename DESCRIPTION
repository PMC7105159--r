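Package: plasmacna
Title: Tumor-Informed Detection of Copy-Number Alterations in Plasma
    Cell-Free DNA from Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for detecting tumor-derived copy-number
    alterations (CNAs) in plasma cell-free DNA sequenced at shallow
    (~0.1x) genome-wide coverage. Per-bin fragment counts are
    GC-corrected, depth-normalized against a healthy-donor reference
    panel, segmented with a permutation-tested recursive binary
    (CBS-style) algorithm, and scored with segmented Z-scores; regions
    altered in a patient's own tumor are then queried in plasma
    (tumor-informed detection) with a direction-matched Z cutoff.
    Includes a synthetic-cohort generator for shallow-WGS bin counts,
    array-like tumor profiles and clinical covariates; donor-panel
    specificity screens; percent-genome-altered summaries; and
    diagnostic-rule evaluation (sensitivity, specificity, predictive
    values with confidence intervals and prevalence adjustment, Welch
    t-tests, mutation recurrence tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
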