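Package: clonalpop
Title: Comparative Population Genomics of Near-Clonal Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of near-clonal microbial genome
    populations, built around anchored whole-genome comparison of assemblies
    against a designated ancestral reference. Discovers core-genome SNPs,
    small indels and multi-nucleotide substitutions, extracts collinear core
    blocks, classifies alleles into singleton, private and shared classes,
    and computes divergence, Tajima's D and Nei-Gojobori dn/ds. Detects
    genomic islands (intervals absent from one or more genomes), types
    nested deletion patterns within an island from read-coverage profiles,
    and compares CRISPR arrays and spacers with Karlin-Altschul e-value
    scoring. Includes a synthetic clonal-population simulator with full
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
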