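Package: retalign
Title: Reticular Progressive Multiple Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Progressive multiple sequence alignment of protein sequences in
    which every guide-tree node retains a network of optimal and suboptimal
    alignments (an x-network) instead of a single alignment.  Networks are
    aligned against networks with a generalised Waterman-Byers
    forward/backward dynamic programme under an affine-gap sum-of-pairs
    scoring scheme with optional guide-tree sequence weighting.  Includes
    neighbour-joining and UPGMA guide trees with mid-point rooting, SP/TC
    alignment accuracy scoring against reference alignments, and a
    tree-based synthetic sequence generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
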