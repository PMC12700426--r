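Package: sostempo
Title: Temporal Hierarchy Analysis of the Bacterial SOS Regulon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the temporal hierarchy of the bacterial
    SOS DNA-damage response from multi-genotype expression data. Implements
    regulon membership calling from negative-binomial exact tests across
    wild-type, repressor-deletion and recA-deletion backgrounds, early/late
    promoter classification, dyad (LexA-box) motif discovery and PWM scoring,
    ChIP coverage normalization with peak-to-gene assignment, single-cell
    induction-time estimation from logistic fits to reporter fluorescence,
    and promoter-strength inference via derepression fold change. A fully
    seeded synthetic-data generator emulates every input layer (annotated
    circular genome, planted operator boxes, count matrices, coverage
    tracks, fluorescence traces) so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
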