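Package: clonodiverge
Title: Morphological Divergence Analysis of Clonal Arthropod Strains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intraspecific morphological divergence among clonal
    (parthenogenetic) strains from per-individual chaetotaxy-style character
    counts. Provides per-character generalized linear model divergence tests
    across strains (likelihood-ratio chi-square, fitted by iteratively
    reweighted least squares), broad-sense heritability by penalized
    quasi-likelihood variance partitioning with a strain random effect,
    coding of strain means into a binary cladistic matrix, exact
    branch-and-bound maximum parsimony with Fitch scoring and strict
    consensus, UPGMA clustering with multiscale-bootstrap approximately
    unbiased (AU) cluster support, and a synthetic clonal-strain data
    generator with known variance components and clade structure so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    nlme,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
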