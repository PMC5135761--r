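Package: stemloop
Title: Stem-Loop (Inverted Repeat) Detection and Structural Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects stem-loop (hairpin) structures in DNA sequences with a
    minimum-penalty dynamic-programming alignment of candidate inverted-repeat
    arms, and summarises them with two family-level statistics:
    length-normalised stem-loop coverage profiles across sets of related
    sequences (e.g. transposon subfamilies such as LINE L1 or SINE Alu
    consensus sets), and pairing-unpairing profiles that localise bulges and
    internal loops within collections of hairpin secondary structures.
    Includes Vienna dot-bracket import/export, a deterministic
    base-pair-maximisation fallback fold, a synthetic-family simulator with
    planted hairpins for benchmarking, BED/TSV exporters, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    optparse,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
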