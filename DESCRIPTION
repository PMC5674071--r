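Package: beadviability
Title: Sum-Intensity Live/Dead Viability Quantification for
    Alginate-Encapsulated Cell Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dual-channel fluorescence (fluorescein diacetate / propidium
    iodide) viability assay for 3-D cell spheroids encapsulated in alginate
    beads, quantified by thresholded sum intensity with matched-channel
    calibration. Includes a synthetic bead-field image generator with known
    per-bead live/dead ground truth (including graded Me2SO-kill presets),
    exposure-time selection by signal-to-noise ratio, low-threshold fitting,
    FDA/PI signal-equivalence matching, bead segmentation, per-bead and
    pooled viability estimates, and perfusion-bioreactor quantifications
    (nutrient-bound monitoring, per-cell oxygen consumption, production
    efficiency, functional-value and secretion-rate normalisations, protein
    AUC, media-to-biomass ratio, and a dissolved-oxygen setpoint escalation
    rule).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
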