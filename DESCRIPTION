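Package: islandmapr
Title: Precise Mapping of tRNA/tmRNA-Gene-Targeted Genomic Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects integrase-encoding genomic islands integrated into
    tRNA and tmRNA genes (tDNAs) of prokaryotic replicons by finding
    displaced tDNA fragments with a seeded local-alignment search,
    passing each tDNA/fragment interval through a cascade of filters
    (integrase, coding-domain, tDNA, length, internal-fragment,
    configuration and orientation), resolving tandem arrays, and naming
    accepted islands with single-nucleotide endpoint precision. Ships a
    seeded synthetic-genome generator that plants truth-annotated
    islands and per-filter decoys, a brute-force local-alignment oracle
    for validating the search, tidy tabular interfaces throughout, and
    a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
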