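Package: helptag
Title: HpaII/MspI Tag Sequencing Analysis of Cytosine Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of HELP-tagging data, a methylation-sensitive
    restriction enzyme sequencing assay. Short sequence tags captured next
    to HpaII (methylation-sensitive) and MspI (methylation-insensitive)
    CCGG cut sites are quality-filtered on a 3' adapter anchor, aligned
    with an exhaustive seed-and-extend strategy, and assigned fractionally
    (1/n) to annotated CCGG sites. Per-site HpaII counts are normalized by
    MspI counts through an angle transformation that scores methylation on
    a 0-90 degree scale with a read-depth confidence distance. The package
    also provides virtual restriction digestion, GC-composition and
    fragment-length bias diagnostics, discovery of polymorphic CCGG sites
    (lost and gained relative to the reference), genomic-compartment
    methylation summaries around transcription start sites, and a seeded
    in-silico library simulator with per-site ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
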