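Package: splicescope
Title: Splice-Junction Extraction, Exon-Skipping and Read-Through Fusion
    Analysis from Spliced Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts exon-exon splice junctions from spliced (gapped) read
    alignments with an overhang rule, classifies splice-site dinucleotide
    motifs (GT/AG, GC/AG, AT/AC, other) against a genome, classifies the
    topology of two-segment read alignments (consistent, scramble, inversion,
    translocation, distant), calls exon-skipping events and local read-through
    gene fusions (transcription-induced chimeras) against a gene annotation,
    normalizes junction counts by library size, and tests events for
    differential usage between two replicate groups with a pooled-variance
    t-test and Benjamini-Hochberg FDR control, including percent-spliced-in
    (Psi) estimates and RPKM fold changes. Ships a seeded synthetic-data
    generator that plants junctions, skipping and fusion events with known
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
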