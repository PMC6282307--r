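Package: homeologr
Title: Allopolyploidy Detection by Gene-Tree/Network Reconciliation and
    Companion Phylogenetic Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to score allopolyploidy hypotheses by reconciling gene
    trees against phylogenetic networks expanded into multi-labeled (MUL)
    species trees under duplication-loss parsimony, to enumerate and rank
    candidate hybridization scenarios, to reconstruct ancestral discrete
    states by stochastic character mapping under an Mk model, to classify
    ploidy from karyotype and homeolog copy-count tables, and to analyse
    genotyping-by-sequencing SNP data by identity-by-state distances and
    classical multidimensional scaling.  Includes synthetic-data generators
    (gene-family birth-death simulation along a species network with genome
    mergers, Mk trait simulation, structured genotype matrices) so the full
    pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
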