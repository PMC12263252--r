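Package: islandOU
Title: Multi-Optimum Ornstein-Uhlenbeck Analysis of Island Body-Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing character displacement in island radiations with
    phylogenetic comparative methods. Implements sympatry-based selective-regime
    assignment, maximum-likelihood fitting of Brownian motion, early-burst and
    single- and multi-optimum Ornstein-Uhlenbeck (Hansen) models with AICc
    comparison, a random-regime null, phylogenetic signal statistics (Pagel's
    lambda, Blomberg's K, Pagel's delta), Brownian-motion ancestral state
    reconstruction with per-regime change accounting, disparity-through-time
    curves with the morphological disparity index, and synthetic-data generators
    (Yule trees, regime-dependent trait evolution, island communities) so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
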