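Package: sedpower
Title: Reaction-Transport Modelling and Cell-Specific Power of Nitrifiers in Marine Oxic Sediments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state one-dimensional finite-volume reaction-transport
    modelling of oxic marine sediments (multi-G organic matter degradation,
    nitrification, denitrification, manganese cycling), coupled to the
    thermodynamics of nitrification (Gibbs energy with extended Debye-Hueckel
    activity corrections, volumetric power supply), an exponential-decay model
    of ammonia-oxidizing archaea relative abundance over the oxic zone, and
    cell-specific power requirements. Includes a synthetic-site generator with
    known ground truth for end-to-end testing, calibration by weighted least
    squares, sensitivity scans, and flux-budget audits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
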