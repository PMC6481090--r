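Package: ampliwell
Title: Genotyping of CRISPR-Edited Clones from Dual-Barcoded 96-Well
    Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of 96-well plate amplicon deep-sequencing
    screens of CRISPR/Cas-edited clones. Paired-end MiSeq reads carrying a
    dual row/column well barcode are demultiplexed to wells, overlapping
    mates are merged back into full amplicon fragments, fragments are
    aligned to the reference amplicon with a semi-global affine-gap
    aligner, and each well's unique alleles are counted and classified
    (wild-type, homology-directed repair, NHEJ indel, substitution,
    complex) to call a per-well genotype. Includes a synthetic plate
    simulator with a truth table for validating the whole pipeline, and
    plain-text/TSV reporting of per-well allele tables and plate success
    rates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
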