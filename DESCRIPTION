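Package: ppctrack
Title: Piecewise Polynomial Models of Run-Length-Encoded Genomic Tracks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds piecewise polynomial curve (PPC) models of genomic
    signal tracks (sequencing coverage, array log-ratios, mappability
    scores) by bottom-up stochastic knot adjustment on run-length-encoded
    input: knots are removed, made continuous, or relocated in randomized
    passes, with every operation gated by a user-selected statistical
    acceptance criterion (relative area deviation, Poisson dispersion, or
    Welch t-test). Includes bedGraph/wiggle readers and writers, a tabular
    PPC format, synthetic-data generators for read coverage, array-CGH
    probe signals, copy-number read depth and RNA-seq exon coverage, and
    downstream analyses: compression metrics, copy-number segmentation
    evaluation, exon-boundary slope diagnostics and CG-content mutual
    information.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
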