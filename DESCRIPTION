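Package: ciphylo
Title: Comparative Analysis of Cytoplasmic-Incompatibility Strength Across
    Wolbachia Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking Wolbachia cif-gene transcript levels, bacterial
    density and host development time to the strength of cytoplasmic
    incompatibility (CI) across a strain phylogeny. Implements CI-strength
    estimation from vial-level hatch data with bias-corrected and accelerated
    (BCa) bootstrap intervals and nonparametric cross-type tests; relative
    qPCR quantification by the 2^-ddCt method with triplicate quality control
    and FDR-adjusted strain comparisons; phylogenetic generalized least
    squares with maximum-likelihood estimation of Pagel's lambda and AIC model
    choice; the Fritz-Purvis D statistic for binary traits with permutation
    and Brownian-threshold nulls plus a tree-size power simulation; pairwise
    protein identity and structure-sequence correlation statistics; and a
    synthetic-study generator with known ground truth for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    boot,
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
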