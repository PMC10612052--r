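Package: virdup
Title: Discovery and Characterization of Internal Duplications in Small
    Viral Genomes from Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing large internal tandem
    duplications in small (viral) genomes from noisy long reads, modelled on
    the discovery of the 3.7 kb duplication in the Sf-rhabdovirus X+ genome.
    Implements k-mer seed-and-chain alignment with back-jump breakpoint
    detection and junction clustering, duplicated-genome reconstruction with
    exact copy-aware coordinate liftover, paralog-aware assignment of variants
    to the primary or duplicated copy, in-silico PCR amplicon enumeration,
    short-read multi-mapping coverage analysis under ignore/random placement
    policies, ORF and intergenic-motif annotation, and a synthetic-data
    generator with rhabdovirus-like genome architecture and configurable
    long/short read error models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    S4Vectors,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
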