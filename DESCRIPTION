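Package: txrefine
Title: Reference-Guided Transcriptome Annotation Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates empirically assembled transcripts (e.g. StringTie
    output) into an existing reference genome annotation. Candidate
    transcripts are screened by splice-junction read support and coverage,
    classified against the reference by intron-chain and exonic-overlap
    comparison into known transcripts, novel isoforms, evidence joining two
    or more neighboring genes, or wholly novel genes, filtered by
    expression support across samples, and fused into an updated annotation
    with a deterministic identifier scheme. Includes summary reporting
    (assembly statistics, gene-merge accounting, gene-level BUSCO
    reconciliation), soft-mask QC, and a seeded synthetic-fixture generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    withr,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
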