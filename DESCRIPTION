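Package: degenr
Title: Degeneracy and Redundancy Measures for Discrete-State Active Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of degeneracy (posterior entropy)
    and redundancy (complexity cost) in discrete-state active inference.
    Provides a Markov-decision-process generative model of a word repetition
    paradigm, variational belief updating with expected free energy based
    policy selection, Dirichlet concentration-parameter learning, structure
    learning by flattening spurious likelihood mappings, precision-based in
    silico lesions of likelihood and transition arrays, free-energy
    decompositions (accuracy/complexity, energy/entropy, cost), behavioral
    accuracy scoring, and simulated evoked (mismatch-negativity style)
    responses derived from belief-updating dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
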