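Package: relacs
Title: In Silico Restriction Digestion, Inline Barcode Demultiplexing and
    Quantitative Normalization for Multiplexed ChIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for restriction-enzyme-based multiplexed
    ChIP-seq experiments in which chromatin is digested and barcoded inside
    intact nuclei before pooling. Provides in-silico digestion of genomes
    with degenerate IUPAC restriction motifs (e.g. the blunt cutter RG|CY),
    restriction-gap ("blind region") and site-density bias analysis against
    chromatin-state annotations, hairpin nuclear-barcode construction and
    decodability validation under a mismatch budget, paired-end inline
    barcode demultiplexing with Hamming-distance assignment, input-based
    median-of-ratios scaling factors, FRiP and FRiP-to-RPKM enrichment
    scores, and a seeded read simulator with a complete ground-truth
    manifest so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
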