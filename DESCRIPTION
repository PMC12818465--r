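Package: cmatsim
Title: Desk-Scale Simulation of Multipoint Adaptive Optics for Mesoscale Two-Photon Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free digital twin of a large field-of-view two-photon
    mesoscope with cellular multipoint adaptive optics. Builds the honeycomb
    grid of wavefront-correction points (hexagon centers plus vertices),
    runs sensorless modal Zernike calibration against seeded synthetic
    phantoms (beads, pollen-like calibration targets, neuron scenes, and
    GCaMP-like calcium movies), simulates tiled and region-of-interest
    scanning with per-tile correction loading, and computes the standard
    image-quality and calcium-signal statistics: Gaussian-fit bead FWHM,
    line profiles, neuropil-subtracted dF/F, SNR, and rank-based group
    comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
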