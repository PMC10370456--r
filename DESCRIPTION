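Package: optforest
Title: Computational Reproducibility of Maximum-Likelihood Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale laboratory for studying computational
    irreproducibility in maximum-likelihood phylogenetics. Simulates
    nucleotide alignments on known model trees under HKY or GTR
    substitution models with discrete-gamma rate heterogeneity and
    autocorrelated lineage rates, infers trees with a seeded internal
    maximum-likelihood engine (Felsenstein pruning, NNI hill climbing,
    retained search traces), quantifies irreproducibility and inaccuracy
    with Robinson-Foulds distances, and constructs the "optimality
    forest" of topologies whose log-likelihood exceeds the true tree's.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
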