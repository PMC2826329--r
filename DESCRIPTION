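Package: recombevol
Title: Phylogenetic Comparative Analysis of Plant Recombination Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how genome-wide and within-gene recombination
    rates evolve across plant lineages. Assembles genome-wide recombination
    rates (cM/Mb) from genetic-map lengths and physical genome sizes with
    marker-density corrections and inclusion filters; tests for phylogenetic
    signal with Blomberg's K and a tip-reshuffling permutation null; computes
    Felsenstein's independent contrasts; fits phylogeny-corrected Gaussian
    regressions of log recombination rate on heterozygosity and life-form via
    generalized least squares with a tree-derived correlation matrix; and
    estimates within-gene recombination from haplotype alignments (Watterson
    and pairwise theta, the Hudson-Kaplan minimum number of recombination
    events, and a Monte-Carlo composite-likelihood population recombination
    rate). A synthetic-data module generates Yule trees, Brownian traits,
    clade-structured life-forms, species tables with known ground truth, and
    coalescent haplotypes with recombination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    picante,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
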