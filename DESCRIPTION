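Package: pgatyper
Title: Genotyping and Variation Analysis of Poly-Gamma-Glutamate Gene
    Clusters in Bacillus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the eleven poly-gamma-glutamate (gamma-PGA) related
    genes (the pgsB-pgsC-pgsA-ywtC/pgsE-pgdS synthetase cluster, racE,
    ggt and the phage-derived hydrolases pghB/pghC/pghL/pghZ) in
    annotated Bacillus genomes by affine-gap protein alignment against a
    reference panel, classifies genomes into cluster-architecture
    genotypes (G1-G7) and subtypes with a declarative rule table,
    catalogs reference-anchored amino-acid substitutions with panel
    frequencies and identity ranges, builds per-enzyme neighbor-joining
    trees with bootstrap support, and computes ninhydrin-assay gamma-PGA
    content and volumetric yield. Ships a synthetic-genome generator
    with planted ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
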