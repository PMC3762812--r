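Package: repeatscape
Title: Repeat Landscape Characterization of Genomic Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Characterizes the repetitive landscape of a set of genomic
    sequences (e.g. BAC or fosmid assemblies). Detects and classifies
    tandem repeats into microsatellite, minisatellite and satellite bins;
    annotates interspersed repeats by homology to a classified repeat
    library using a gap-adjusted similarity (sim) metric and a modified
    80-80-80 full-length filter; discovers repeat families de novo through
    self-alignment seed discovery, full-length instance extraction,
    identity-threshold clustering, consensus building and family merging;
    assigns hierarchical transposable-element classifications from
    nucleotide, protein and structural evidence (LTR pairs, PBS, PPT,
    poly-A tails, ORFs); and produces per-category coverage reports.
    Includes a synthetic-genome simulator that plants repeat families and
    tandem arrays with exact ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    igraph,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
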