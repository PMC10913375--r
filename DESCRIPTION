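Package: terenrich
Title: Terminus-Region Enrichment Analysis of Vesicle DNA Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing DNA packaged in bacterial outer membrane
    vesicles from mapped sequencing reads: per-nucleotide coverage along
    circular replicons, sliding-window summaries, a terminus-of-replication
    (dif-region) enrichment statistic against a null of 200 random
    equally sized non-ter windows, TMM-normalized between-strain log2
    fold-change of ter-region coverage, and a seeded read-position
    simulator so every stage is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
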