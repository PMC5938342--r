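Package: bgalleles
Title: Functional-Allele Assignment and Coiled-Coil Analysis for Chicken BG Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cDNA clone libraries of the polymorphic
    chicken BG (butyrophilin-family) genes. Clones are segmented against a
    canonical BG gene model (5'UTR/signal exon, Ig-V exon, transmembrane exon,
    many 21-nucleotide repeat exons, final exon), retained introns are
    detected, conceptual transcripts are reconstructed and translated with
    phase-1 split codons, clones are collapsed into putative genes by exact
    exon-2 identity and named by frequency, PCR chimeras and likely
    mis-incorporation singletons are flagged, heptad registers of the
    cytoplasmic-tail coiled-coil are assigned via the split-codon rule, and
    region-wise silent versus replacement variation is counted. A seeded
    synthetic-data generator produces BG-like gene families and clone
    libraries with full ground truth so every stage of the pipeline can be
    validated.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
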