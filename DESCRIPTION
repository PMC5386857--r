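Package: refstab
Title: Reference Gene Selection and Validation from Whole Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and validates stably expressed qPCR reference
    (housekeeping) genes from multi-tissue, multi-batch RNA-seq expression
    matrices. Implements a coefficient-of-variation (CV) ranking screen with a
    minimum-expression filter, a pairwise log fold-change exclusion screen with
    library-size (CPM) normalization, an efficiency-corrected delta-Cq qPCR
    analysis arm (dilution-series efficiency estimation, technical-replicate
    outlier handling, calibrator normalization, qPCR stability CV, 3'/5'
    integrity QC), cross-batch and cross-platform Pearson concordance
    analytics, and a seeded negative-binomial synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
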