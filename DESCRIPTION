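Package: efedesign
Title: mRNA Sequence Design by Ensemble Free Energy Optimization over
    Codon Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Designs messenger RNA coding sequences for a target protein by
    minimizing ensemble free energy rather than minimum free energy. The
    synonymous design space is represented compactly as a layered
    deterministic finite automaton (a codon lattice); a probabilistic
    relaxation places per-node edge probabilities on the lattice and the
    expected Boltzmann partition function over the induced sequence
    distribution is maximized by projected gradient ascent, with gradients
    from an inside-outside dynamic program. Includes a joint
    sequence-structure minimum-free-energy design baseline (Viterbi lattice
    parsing), a random-walk baseline, exact Nussinov-level folding
    (minimum free energy, partition function, base-pairing probabilities),
    evaluation metrics (ensemble free energy, average unpaired probability,
    positional structural entropy), beam-pruning diagnostics, and a
    synthetic protein panel generator for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
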