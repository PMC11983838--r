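Package: highmt
Title: Analysis of Malignant Cells with High Mitochondrial RNA Content in
    Single-Cell and Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterize viable malignant cells with a
    high percentage of mitochondrial RNA counts (pctMT) in cancer single-cell
    and spatial transcriptomics. Implements quality control that deliberately
    avoids mitochondrial-content filtering, per-patient HighMT odds-ratio
    case/control annotation, bin-controlled gene-signature scoring, metacell
    aggregation, a bulk versus "bulkified" polynomial-residual test with an
    empirical gene-sampling null, pathway dysregulation summaries, cell-line
    drug-sensitivity correlation with permutation calibration, and spatial
    patch statistics. A synthetic-data generator with plantable ground-truth
    effects makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
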