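Package: ecompass
Title: Evaluative Comparison of Large Multiple Protein Sequence Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides which of two multiple sequence alignments (MSAs) of the
    same large protein set is the more accurate, by measuring the statistical
    congruence between alignment-derived direct-coupling scores (average
    product corrected Frobenius norms of a pseudo-likelihood Potts fit) and
    residue contacts observed in reference 3D structures. Per-structure
    S-scores are combined into a majority vote with a two-tailed binomial
    P-value, after iterative exclusion of structures whose Calpha
    distance-matrix discrepancy marks them as likely misaligned. A Potts-model
    simulation harness generates gold-standard alignments with planted contact
    graphs, applies controlled corruptions, and validates the score against
    sum-of-pairs alignment accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
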