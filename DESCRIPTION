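Package: gbmeth
Title: Gene-Body Methylation Analysis from Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing invertebrate gene-body DNA methylation from
    whole-genome bisulfite sequencing (WGBS) coverage files. Implements
    spike-in-calibrated binomial methylation calling with Benjamini-Hochberg
    false discovery rate control, weighted methylation levels per genomic
    feature, transposable-element context classification, coupling of
    differential methylation to differential gene expression, expression
    stability analysis, CpG observed/expected (O/E) depletion statistics with
    Gaussian-mixture decomposition by expectation-maximisation, reciprocal
    best-hit ortholog pairing with codon-alignment filtering, and a
    synthetic-data generator that emulates the statistical structure of a
    bimodally methylated invertebrate genome for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
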