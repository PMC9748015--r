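Package: condensr
Title: Lattice Sticker-and-Spacer Simulations and Analyses of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Metropolis Monte Carlo simulation of sticker-and-spacer polymer
    models of prion-like low-complexity domains on a periodic cubic lattice,
    together with the analyses used to characterise phase separation coupled
    to percolation: coexistence curves (binodals) and the two-phase width,
    ERMSL comparison of dilute arms, swelling ratios and their master curve,
    overlap concentrations, ternary contact fractions, condensate contact
    graphs with betweenness and small-world statistics, discrete-Weibull
    sticker-cluster statistics, and radially resolved interface profiles with
    hyperbolic-tangent fits. Includes deterministic synthetic-fixture
    generators with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
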