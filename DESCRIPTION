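Package: suvrkit
Title: Integrative Analysis of Sequence-Directed H3K9me2 Silencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative analysis of a zinc-finger-guided
    H3K9 methyltransferase pathway: position-weight-matrix motif discovery
    from SELEX read pools with exact score-distribution p-values, tiling-array
    H3K9me2 differential-region calling by Z-score, context-resolved (CG/CHG/CHH)
    bisulfite methylation summaries, RPKM plus Fisher-exact differential
    expression with Benjamini-Hochberg correction, and interval-level
    integration of all layers. A synthetic-data module generates multi-layer
    genomes with planted ground truth so every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
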