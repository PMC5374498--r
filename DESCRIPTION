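Package: mircaste
Title: Small RNA-Seq Pipeline for Interval-Overlap and Offset Fold Change
    Analysis of miRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying mature microRNA expression
    from multi-library small RNA sequencing experiments and calling
    differential expression between phenotype groups. Reads are cleaned by
    3' adapter and high-definition (HD, degenerate-base) signature trimming,
    collapsed to unique tags, mapped full length and ungapped to a genome
    within a mismatch bound, assigned to a mature miRNA catalog, normalized
    by read count per total to a fixed library size, and tested for
    differential expression with a maximal expression interval overlap rule
    combined with a log2 offset fold change (OFC) threshold. A synthetic-data
    generator produces genomes, miRNA catalogs and FASTQ libraries with known
    spiked fold changes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
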