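Package: basalshift
Title: Basal-State Shift and Immune-Activation Analysis for ER+ Breast Cancer Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify acquisition of basal-like transcriptional state
    and immune activation in estrogen-receptor-positive breast cancer cohorts.
    Implements single-sample gene-set enrichment (kernel-ECDF GSVA statistic and
    rank-weighted ssGSEA), paired metastasis-minus-primary delta scoring,
    luminal/basal signature derivation from labeled reference panels,
    nearest-centroid subtype calling, cross-comparison fold-change concordance,
    weighted tumor mutation burden from MAF tables, immune and immune-cell-type
    scoring with quartile stratification and pathway intersection, Kaplan-Meier,
    log-rank and Cox survival comparisons, and insulated-neighborhood boundary
    and chromatin-loop logic from CTCF/cohesin peak tracks. Includes seeded
    synthetic-data generators with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    survival,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
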