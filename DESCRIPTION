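Package: tsitescreen
Title: In Silico Screening of Insecticide Target Sites in Insect Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparative in-silico assessment of insecticide
    target-site genes in an annotated insect genome. Assigns orthologs by
    local protein search with coverage and E-value thresholds, maps predicted
    transcripts back to genomic loci to classify GT-AG alternative-splicing
    events and enumerate isoform space, calls candidate A-to-I RNA-editing
    sites from genome-versus-transcriptome mismatches, projects a catalog of
    known resistance mutations onto query orthologs and calls the state of
    each site, scans proteins with PROSITE-style motif patterns and a
    channel-feature catalog, and builds neighbor-joining trees with
    bootstrap supports from progressive protein alignments. Ships a
    synthetic-genome generator with truth tables so every stage can be
    exercised end-to-end without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
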