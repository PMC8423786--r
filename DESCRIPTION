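Package: sigshare
Title: Cross-Dataset Transcriptional Signature Sharing for Single-Cell and Bulk Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative transcriptional-identity analysis for single-cell and
    single-nuclei RNA-seq together with bulk clinical cohorts. Detects
    cluster-specific gene signatures with one-vs-each Welch tests, measures
    signature sharing between datasets (including cross-species comparisons
    restricted to one-to-one orthologs) with one-sided Fisher enrichment,
    scores cells against reference signatures with a seeded random-background
    control, tests cluster composition against clinical groupings, aggregates
    per-cell copy-number states over genomic regions and tests clonal
    enrichment per cluster, scans optimal survival cutpoints with log-rank
    tests, and builds bootstrap-supported cluster dendrograms. Ships a seeded
    negative-binomial simulator that plants markers, shared signatures, CNV
    clones and survival-linked bulk cohorts so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
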