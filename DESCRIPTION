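Package: circlip
Title: Detection and Characterization of RBP-Bound Circular RNAs from CLIP-Seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies circular RNAs bound by RNA-binding proteins from CLIP-Seq
    data. Builds a pseudo-reference of linearized back-splice junction contigs,
    competitively classifies junction-spanning reads against the combined
    junction-plus-genome reference, applies multi-rule candidate filtering, and
    provides downstream characterizations: strand bias, binding-profile
    clustering of proteins by shared circRNA targets, randomization-corrected
    hypergeometric gene-set enrichment, and motif foreground/background
    sequence export. Includes a seeded synthetic-data generator and an
    exhaustive ungapped aligner used as a testing oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    fgsea,
    ape,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
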