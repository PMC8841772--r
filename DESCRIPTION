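Package: aortapwv
Title: Aortic Pulse Wave Velocity from Ultrafast Curved-Array Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and measurement toolchain for local aortic pulse wave
    velocity (PWV) from ultrafast curved-array ultrasound. Provides a synthetic
    phantom generator (propagating wall-displacement fields, point-scatterer
    speckle, pressure waveforms, risk-stratified cohorts), delay-and-sum
    beamforming of tilted diverging-wave transmissions with coherent
    compounding, adaptive-reference-frame speckle tracking of axial wall
    motion, spatiotemporal PWV imaging with 50%-upstroke time-distance
    regression and an r-squared reliability gate, the Bramwell-Hill
    distensibility-based theoretical PWV, and the accompanying statistical
    battery (Kruskal-Wallis with Dunn-Bonferroni post hoc, Welch t, Pearson
    correlation, Bland-Altman agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    rhdf5,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
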