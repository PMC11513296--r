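Package: sawoce
Title: Surface Acoustic Wave Velocity Estimation and Deep Regression for
    Optical Coherence Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for wave-based optical coherence elastography (OCE) of
    soft tissue. Provides a synthetic raw-phase volume generator with known
    surface-acoustic-wave (SAW) velocity, the conventional phase-difference /
    directional-filter / time-of-flight velocity estimation stack used to
    produce ground-truth labels, a compact squeeze-and-excitation
    convolutional regression network (VP-Net, in three size variants) with a
    self-contained training engine, gradient-weighted class activation maps
    for the scalar velocity output, and conversion of SAW velocity to bulk
    Young's modulus under the Rayleigh surface-wave model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
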