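Package: scingest
Title: FAIR Single-Cell Metadata Brokering, Browser Tracks and Regulatory
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for making single-cell transcriptomics
    submissions FAIR. Validates FAANG-style submissions (sample, experiment
    and analysis documents) against a configurable three-tier ruleset,
    brokers them into a Human Cell Atlas style experimental entity graph
    (projects, biomaterials, protocols, processes, files and links) with
    deterministic UUIDs and schema references, collapses genes-by-cells
    expression matrices into per-cell-type barChart BED tracks for genome
    browsers, and infers ranked transcription-factor to target-gene
    regulatory networks with a tree-ensemble importance method. Ships a
    synthetic fixture generator (PBMC-like submission, planted linear
    network, toy gene annotation) so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    digest,
    GenomicRanges,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    randomForest,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
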