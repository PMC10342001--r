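Package: fmodyn
Title: Exciton Dynamics and Multipartite Entanglement in FMO Monomers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-Markovian simulation and entanglement analysis of
    excitation-energy transfer in single monomers of the Fenna-Matthews-Olson
    (FMO) light-harvesting complex. Provides a hierarchical-equations-of-motion
    (HEOM) propagator for the eight-bacteriochlorophyll site Hamiltonian with
    Drude-Lorentz dephasing and reaction-centre trapping, a suite of
    bipartition-based entanglement and coherence measures (concurrences,
    l1-norm coherence, negativity and logarithmic negativity, relative entropy
    of coherence, Meyer-Wallach, weighted bipartition averages), the geometric
    entanglement measure via maximum fidelity to the closest fully separable
    state for pure and mixed multi-qubit states, and a permutation-based
    tracker of excitation-state transference under the Uhlmann fidelity.
    Includes generators for FMO-like synthetic Hamiltonians and random test
    states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
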