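Package: knocktag
Title: Design and Junction Analysis for NHEJ-Based CRISPR Knock-In Tagging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for homology-independent (NHEJ-mediated) CRISPR knock-in
    tagging of protein C termini. Enumerates SpCas9 target sites (20-nt
    protospacer + NGG PAM) near stop codons of annotated coding genes,
    computes the open-reading-frame bases and amino acids lost on tagging,
    filters sites whose junction would reconstitute a cleavable target, and
    selects one optimal site per gene. Models a universal tag donor that is
    cleavable at three adjacent positions within a poly-G stretch (the
    reading-frame selectors), predicts genome-donor fusion alleles and
    fusion proteins for either integration orientation, and designs scarless
    donor inserts that re-encode lost codons with synonymous re-cutting
    protection. Classifies amplicon deep-sequencing reads at knock-in
    junctions into seamless, deletion, insertion and frame-shift events,
    including the recurrent single-base duplication of the donor base at
    PAM position -4, and aggregates integration-fidelity and locus
    genotyping reports. A simulation module generates synthetic genomes,
    gene models and junction read sets with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
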