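Package: cfba
Title: Conditional Flux Balance Analysis in Cyclic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based prediction of optimal metabolic trajectories in
    cyclic environments by conditional flux balance analysis (cFBA). A
    stoichiometric network is partitioned into quasi-steady-state (balanced)
    metabolites and explicitly time-resolved (imbalanced) species such as
    enzymes, storage polymers and biomass components. Given enzyme-capacity
    (kcat) constraints, composition quotas and piecewise-constant environment
    bounds, the package discretizes the cycle, assembles a linear feasibility
    program for each candidate per-cycle multiplication factor, and maximizes
    that factor by binary search. Includes an SBML-based interchange format,
    tabular model input, analytic and randomized test fixtures, trajectory
    post-processing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
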