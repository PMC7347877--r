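Package: domainweaver
Title: Two-Condition Integration of Chromatin Architecture and Epigenome Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies two-condition (control versus knockout) changes in
    chromatin architecture and epigenome features from processed genomics
    files: contact-domain and loop interaction strength on observed-over-
    expected KR-normalized Hi-C matrices, boundary insulation, A/B
    compartment eigenvectors oriented by H3K27ac, aggregate peak analysis
    with peak-to-lower-left scores, regulatory-element classification from
    DNaseI and histone-mark peaks, per-domain accessibility fold-change
    classes, strand-specific enhancer RNA quantification, and a
    distance-controlled resampling null comparing boundary-loop and
    intra-domain interaction changes. Ships a synthetic-data generator with
    planted effect sizes so every stage can be validated against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
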