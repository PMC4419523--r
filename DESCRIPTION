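Package: memhnn
Title: Behavioural Simulation of a Memristive Hybrid Neural Network for
    Imagined-Speech EEG Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Behavioural simulator of a single-layer hybrid neural network
    built on a PCMO memristive cross-point synapse array, together with the
    EEG front-end that feeds it. Provides a threshold-gated, state-dependent,
    saturating conductance model of one memristive synapse; a 32x6 crossbar
    with a modified half-bias potentiation/depression learning scheme; leaky
    integrate-and-fire post-neurons; pairwise first-to-fire decision logic
    over three vowel classes; and an EEG feature-extraction chain (Butterworth
    band-pass, multivariate empirical mode decomposition, alpha-band mode
    selection, common spatial patterns, 32-bit binarization). Seeded
    generators for synthetic EEG and synthetic feature codes make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
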