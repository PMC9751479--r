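Package: ervkit
Title: Simulation, Discovery, Dating and Typing of HML2-Like Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the genomic footprint of HML2-like endogenous
    retroviruses (ERVs). The package simulates multi-species genome cohorts with
    planted proviral insertions of known age and structure, discovers proviral
    loci by seed-and-extend scanning, classifies cross-species orthology from
    flanking sequence, dates integrations from LTR and consensus divergence with
    CpG masking, annotates proviral structure, residual coding capacity and
    protein motifs, classifies env subtypes and variants, detects env
    recombination by two-parent minimal-mismatch segmentation, and builds
    bootstrapped neighbor-joining phylogenies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    tibble,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
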