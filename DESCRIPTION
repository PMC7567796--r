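Package: HTGTSjunctions
Title: Junction Calling and Classification for Bait-Primed Translocation Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls and classifies DNA break-repair junctions from
    LAM-HTGTS-style bait-primed sequencing libraries and from locus-capture
    pull-down libraries. Provides bait-primer filtering, adapter trimming and
    read-pair overlap merging, a seed-and-extend split-read aligner for
    mini-genomes, ingestion of external SAM alignments, a decision tree that
    assigns each read to germline, repeat, adjacent-segment or bait-junction
    categories, microhomology and untemplated-insertion calling at junctions,
    RSS-anchored DNA end-resection quantification, capture-mode V-V/V-J join
    classification, and library-level summaries with genome-track and arc
    exports. A seeded synthetic-library generator builds a mini-genome and
    read pairs with full per-read ground truth so every pipeline stage can be
    validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
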