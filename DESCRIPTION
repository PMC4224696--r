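Package: oncocis
Title: Cell-Type-Aware Annotation and Prioritization of Cis-Regulatory
    Cancer Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates candidate non-coding cancer mutations with
    cell-type-specific chromatin context (DNase I hypersensitive sites and
    flanking H3K4me1/H3K4me3/H3K27ac histone marks), transcription factor
    binding motifs created or removed by the mutation (position weight
    matrix scanning with a conserved-position stringency filter), mammalian
    sequence conservation, target gene assignment via enhancer-TSS
    associations or nearest transcription start site, and mutation-linked
    differential expression against matched expression data. Includes a
    bootstrap test for interval-overlap enrichment, a prioritization filter
    for candidate cis-regulatory mutations, and a seeded synthetic cohort
    generator for validation.
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
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
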