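Package: hypercoop
Title: Evolutionary Games with Order-Dependent Strategies on Higher-Order
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulator for multi-player social dilemmas on
    random-regular hypergraphs built from pairwise edges and three-player
    hyperedges (triangles). Players carry an order-dependent strategy vector
    (one slot per interaction order), accumulate payoffs from a pairwise
    prisoner's dilemma and a comparability-constrained three-player payoff
    cube with tunable dilemma strength, and imitate neighbours through the
    Fermi rule with an inter-order coupling probability. Includes a
    configuration-model generator for three-regular simplicial complexes,
    degree-preserving criss-cross rewiring to tune the edge-hyperedge
    topological overlap, a quasi-stationary method for the absorbing
    dynamics, exact small-system Markov chain solvers, and ensemble sweep
    drivers for stationary cooperation-density phase diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
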