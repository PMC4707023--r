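Package: gsgpr
Title: Geometric Semantic Genetic Programming with Elitist Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A geometric semantic genetic programming (GSGP) engine for
    symbolic regression. Individuals are represented by their semantics
    (output vectors on the training and test partitions) plus lineage
    references, so crossover and mutation cost O(n) per offspring and
    unseen instances are evaluated in time linear in the number of
    generations. Implements elitist replacement operators that accept an
    offspring only when it is strictly fitter than its parent(s),
    controlling the exponential program-size growth of standard GSGP,
    with exact (arbitrary-precision) node-count accounting, a theoretical
    average-size bound, manageability-horizon detection against the
    depth-17 node budget, rank-based comparison of final model sizes, a
    synthetic QSAR-like benchmark generator, and a multi-run experiment
    harness with tidy outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
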