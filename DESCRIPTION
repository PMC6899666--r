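Package: splicecov
Title: Splice-Variant Coverage Congruency Scoring for RNA-Seq Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless engine for scoring RNA-seq samples against the splice
    variants of a gene. Extracts per-nucleotide read depth and region read
    counts from indexed BAM files, represents gene models parsed from GFF3 as
    typed exon/CDS/UTR interval sets, and scores the congruency between a
    sample's coverage profile and each splice variant's dichotomous exon mask
    with the point-biserial correlation coefficient. Expression is summarized
    as absolute RPKM (reads per kilobase of exon per million mapped reads) and
    as control-relative log2 ratios, including a median-as-control atlas mode.
    Sample compendia are described by an extended annots.xml-style
    configuration; results are assembled into sortable, filterable tables with
    TSV/CSV/JSON export, coverage and gene-structure plots, and
    expression-to-color mapping on yellow-red and blue-yellow-red scales. A
    deterministic simulator generates multi-isoform toy genes and spliced
    short-read alignments from known isoform mixtures so the whole engine is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
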