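Package: motifbag
Title: Bag-of-Motifs Classification and Interpretation of Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents distal cis-regulatory elements (CREs) as unordered
    counts of transcription factor binding motifs and trains gradient-boosted
    tree models to classify cell-type- or condition-specific elements.
    Includes a position weight matrix scanner with exact p-values computed by
    dynamic programming and Benjamini-Hochberg q-value filtering, balanced
    dataset assembly with stratified backgrounds, per-element Shapley motif
    attributions with an exact enumeration oracle, cross-species single-cell
    type assignment from aggregated attributions over accessible marker
    peaks, synthetic regulatory element design by motif implantation, and
    simulators for labeled CRE sequence sets and cell-by-peak accessibility
    matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    Matrix,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
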