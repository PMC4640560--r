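Package: mirovary
Title: Ovarian MicroRNA Profiling, Curation and Age-Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for quantifying small-RNA reads on microRNA
    hairpin precursors and analysing ovarian miRNA transcriptomes. Maps
    collapsed reads onto precursor arms, computes 5'-start (isomiR)
    homogeneity, applies a curation cascade (contaminant removal, both-arm
    rule, 95% homogeneity rule, per-sample dominant-arm read-count cutoffs),
    classifies miRNAs by evolutionary age from species catalogues, normalises
    expression to reads per million miRNA reads, calls tissue-enriched
    ("ovary set") miRNAs by fold change against a whole-body reference
    library, and runs the rank statistics relating miRNA age to expression
    level. Includes a seeded synthetic-data generator with planted ground
    truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
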