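Package: polyanno
Title: Homopolymer-Aware Annotation of Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation toolkit for mitochondrial genomes whose coding regions
    carry long poly-T insertions that are collapsed to 6-mers in the mature
    transcripts, as observed in appendicularian tunicates. Provides
    homopolymer-run profiling of circular sequences, a poly-T RNA-editing
    model with an exact genome-to-transcript coordinate map, affine-gap local
    (Smith-Waterman) alignment in nucleotide and protein space with
    edit-aware gap classification, ORF discovery and gene annotation under
    the ascidian mitochondrial genetic code (translation table 13),
    structural validation of the poly-A gene-spacing grammar, and a
    synthetic-mitogenome simulator with full ground truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
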