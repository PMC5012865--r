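Package: vesnet
Title: Boolean Vesicle Traffic Networks and Cisternal Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cell-wide vesicle traffic as a deterministic Boolean
    dynamical system in which compartment and vesicle identities are binary
    molecular-label vectors and the dynamics are fixed by a pair of random
    budding and fusion rule matrices. Discovers homeostatic (period-1)
    compartment networks by sampling rules across a parameter grid, converts
    them to typed traffic graphs (vesicle, creation, and maturation edges),
    and analyses their anatomy: maturation chains and cycles, exhaustive
    three-compartment motif enumeration with isomorphism canonicalization,
    degree-preserving edge-swap null models, retrograde-vesicle statistics,
    and molecular-sink detection. Also includes a microscopic counterpart of
    the maturation chain (exact Gillespie simulation of a two-label
    budding/fusion reaction system, its mean-field ODE limit cycle and linear
    stability condition) and a force-directed spatial layout optimizer that
    quantifies the spontaneous stacking of maturation chains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
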