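Package: lumfish
Title: Repeated Origins and Diversification of Bioluminescence on Time Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative phylogenetic pipeline for counting independent
    evolutionary origins of a binary trait (bioluminescence in ray-finned
    fishes) and detecting exceptionally species-rich trait-bearing clades.
    Implements the two-state Mk model with Felsenstein pruning, Bayesian
    MCMC over gain/loss rates integrated across a posterior sample of
    time-calibrated trees, marginal ancestral-state reconstruction,
    absence-to-presence transition counting with mechanism classification,
    Magallon-Sanderson birth-death clade-size envelopes, and a stepwise
    AICc diversification-rate-shift search with terminal richness. A
    synthetic-data module simulates birth-death trees, Mk traits and clade
    richness tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    Matrix,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
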