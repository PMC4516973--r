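Package: DNBdetect
Title: Dynamical Network Biomarker Detection in Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies dynamical network biomarkers (DNBs): gene modules whose
    rising fluctuation, rising internal correlation and falling correlation with
    the rest of the transcriptome jointly give an early-warning signal of an
    imminent critical transition in a case/control time course. Provides
    probe-to-gene preprocessing for GEO series-matrix tables, per-time-point
    correlation clustering, the composite DNB score, dominant-module selection
    with transition detection, a size-matched bootstrap null, fixed-module
    cross-dataset scoring, hypergeometric over-representation analysis, network
    export, and a fully parameterised near-bifurcation simulator with planted
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    igraph,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
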