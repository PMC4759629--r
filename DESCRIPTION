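Package: cotfold
Title: Chemical Kinetics of Co-Translational Protein Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts in-vivo co-translational folding curves of protein
    domains from bulk folding and unfolding rates and codon translation
    rates, using a two-state chemical kinetic model of translation
    elongation coupled to folding. Implements the pulse-chase labelling
    bookkeeping that maps the model onto radiolabelling experiments, the
    steady-state nascent-length folding profile and its co- versus
    post-translational classifier, an event-driven Gillespie stochastic
    simulator used as ground truth, codon translation-rate scaling and
    slowest-synonymous recoding utilities, and three-region rank-sum
    statistics for folding-versus-length (FactSeq-style) signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
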