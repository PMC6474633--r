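Package: hierlearn
Title: Hierarchical and Flat Ideal Observers for Change-Point Learning Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative model and ideal-observer analyses for a binary
    sequence-learning task in which two transition probabilities change
    abruptly at unpredictable change points. Implements a hierarchical
    Bayes-optimal observer (forward filtering of a discretized change-point
    hidden Markov model), a flat leaky-count Beta observer equivalent to a
    confidence-extended delta rule, grid-search parameter fitting against
    generative probabilities or subject reports, the streak-based
    confidence-reset hallmark analysis that dissociates hierarchical from
    flat learning, simulation studies of apparent learning rate and
    cross-model correlation, and synthetic-subject generation with I/O in
    a nine-column per-trial matrix layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
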