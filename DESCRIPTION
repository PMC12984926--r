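Package: phoscoreg
Title: Co-Regulation Screening of Kinase Phosphosites Across Phosphoproteomic Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the predominant phosphosites of a kinase from
    heterogeneous phosphoproteomic corpora and screens phosphosites on other
    proteins for positive or negative co-differential regulation with them.
    Ingests per-condition differential records and per-dataset profiling
    records, applies class-1 localization filtering and fold-change based
    up/down calling, ranks sites by detection frequency, pairs a predominant
    anchor site against every other site to form 2x2 co-detection contingency
    tables, and tests association with a from-scratch two-sided Fisher's exact
    test with stringent evidence filters (study and condition support).
    Also scores window-based phosphosite conservation in a family multiple
    sequence alignment, overlays kinase/substrate/interactor annotation
    tables, runs hypergeometric over-representation analysis, exports
    annotated co-regulation networks (SIF, TSV, GraphML), and ships a
    synthetic-corpus generator with planted co-regulated partners for
    end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    stats,
    utils,
    withr,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
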