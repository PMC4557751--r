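Package: hicapr
Title: Promoter-Capture Hi-C Interaction Calling and Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("hicapr", "developers", email = "hicapr@example.org", role = c("aut", "cre"))
Description: Tools for the computational arm of promoter-capture Hi-C (HiCap)
    experiments: in-silico restriction digestion and promoter probe-target
    design, read-pair filtering (duplicate, self-ligation and same-fragment
    removal, on-target selection), replicate-thresholded calling of
    promoter-distal, promoter-promoter and distal-distal interactions, and
    downstream statistics: enhancer-feature enrichment against a
    distance-matched background, TAD containment, enhancer-RNA expression,
    transcription-factor perturbation validation, and typed network motif,
    clique and gene-ontology sharing analyses with degree-preserving
    randomization. A seeded simulator generates capture Hi-C data with planted
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
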