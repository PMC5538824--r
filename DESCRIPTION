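Package: cabuffer
Title: Calcium Buffering, Excitability and Mitochondrial Release Analysis for
    Fura-2 Imaging and Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of neuronal calcium handling and excitability from
    ratiometric fura-2 imaging and current-clamp recordings. Implements
    equilibrium speciation of chelator-containing calibration solutions
    (EGTA, fura-2) with ionic-strength and temperature corrections,
    ratiometric calibration of fluorescence ratios to free calcium
    concentrations, the added-buffer estimation of the endogenous
    calcium-binding ratio and extrusion rate with fixed-x residual
    bootstrap, spike-frequency-adaptation and excitability metrics,
    FCCP-evoked mitochondrial calcium-release quantification, and a
    forward simulator of all supported recording types with known ground
    truth for validation by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
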