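Package: baitlink
Title: Viewpoint 4C-seq Processing and Enhancer Target-Gene Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking a single chromatin viewpoint (a 4C-seq
    "bait", such as a risk-SNP enhancer) to its candidate target genes.
    Implements in-silico restriction digestion and fragment maps,
    viewpoint-anchored paired-end read demultiplexing, per-fragment
    reads-per-million coverage, reproducibility-filtered interaction
    calling with cis/trans classification, integration with differential
    expression tables to nominate target genes, efficiency-corrected
    3C-qPCR quantification from standard curves, allele-specific
    position-weight-matrix scoring at a SNP, and seeded simulators that
    generate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
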