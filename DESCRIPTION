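Package: viscsf
Title: Spatio-Temporal Contrast Sensitivity Modelling and CSF-Weighted Video Quality
Version: 0.1.0
Authors@R:
    person("viscsf", "developers", email = "viscsf@example.org", role = c("aut", "cre"))
Description: Tools for modelling the spatio-temporal contrast sensitivity
    function (CSF) of the human visual system under modern display conditions.
    Synthesizes the "Mira" Kaiser-windowed sinusoidal grating stimulus and its
    analytic spatial spectrum, models the display channel (gamma calibration,
    pixel geometry, cycles-per-degree conversion), simulates method-of-limits
    threshold experiments with a BT.500-style sequential stopping rule, fits
    polynomial visibility surfaces by ridge regression with an unpenalized
    intercept, and uses any fitted CSF surface as a frequency-domain perceptual
    weight inside a weighted-PSNR video quality metric with logistic mapping to
    subjective scores and Fisher-z correlation bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
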