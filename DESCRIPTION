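Package: selexarray
Title: SELEX-Seq Motif Enrichment, Spacing Grammar and CLIP Binding-Index Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deriving and validating multi-element RNA
    recognition models of multidomain RNA-binding proteins from in vitro
    selection (SELEX-seq) data. Implements preprocessing of selection-round
    reads (demultiplexing, adapter trimming, random-barcode deduplication),
    k-mer containment counting with control-corrected z-score enrichment,
    ordered tetramer-pair spacing analysis over 0-25 nt gaps with
    motif-class spacing profiles, a motif-array grammar scanner for
    transcript regions (GGC-core anchors enclosing margined CA elements),
    and a CLIP-tag binding index with Welch group comparisons. A
    synthetic-data module simulates selection rounds with planted motif
    affinities and pair spacings, builds a designed 101-mer fixture series,
    and generates a synthetic regulome (regions, planted arrays, expression,
    CLIP tags) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
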