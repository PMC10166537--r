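Package: hyperphylo
Title: Bayesian Phylogenetic Inference by MCMC in Hyperbolic Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian phylogenetic inference by Markov chain Monte Carlo over
    embeddings of taxa in the hyperboloid (Lorentz) model of hyperbolic space.
    Taxa are embedded from sequence or tree distances by a strain/stress
    (hydra-style) procedure, Gaussian moves are proposed in the tangent space
    at the origin, a neighbour-joining tree is decoded from the pairwise
    hyperbolic distances at every generation, and states are scored by a
    Jukes-Cantor (JC69) pruning likelihood with a Gamma-Dirichlet prior on
    branch lengths. Includes Metropolis-coupled chains with robust adaptive
    Metropolis proposals, convergence diagnostics (split frequencies, ASDSF,
    tree-length summaries), posterior-landscape and proposal-neighbourhood
    instruments, and a JC69 simulator for synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tibble
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
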