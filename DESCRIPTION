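Package: unitssl
Title: Unit Structures and the Strengthened Second Law for Composite
    Markov Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the information thermodynamics of multi-dimensional
    continuous-time Markov chains coupled to multiple reservoirs.  Builds
    reservoir-structured rate matrices with puppet and leader coordinate
    sets, validates unit structures (coordinate subsets whose marginal
    dynamics is a self-contained Markov chain), integrates the master
    equation, and computes entropy flow and entropy production globally
    and per unit.  Implements the inclusion-exclusion ("in-ex")
    information of a unit structure, the resulting decomposition of
    entropy production, a strengthened second-law lower bound for
    height-2 dependency graphs, and information bounds on work extraction
    under feedback control.  Ships reproducible example systems: a
    cell-sensing network of four subsystems, a three-subsystem
    conditional relaxation, and a coarse-grained lattice random walker
    with nutrient stores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
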