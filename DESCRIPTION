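Package: sheepvitals
Title: Non-Contact Sheep Vital Signs from RGB and Radiometric Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for camera-based livestock heat-stress monitoring. Extracts
    heart rate and respiration rate from RGB video of a tracked nose region via
    photoplethysmographic luminosity signals (green channel for heart rate,
    CIELAB a* for respiration), using zero-phase Butterworth band-pass
    filtering, FFT peak estimation, a band-classifying feedforward neural
    network and a Bayesian-regularized regression network. Also computes
    region-of-interest temperature statistics from radiometric thermal frame
    stacks, the sheep temperature-humidity index, through-origin regression
    diagnostics, and ships a synthetic scene generator with known ground truth
    so the whole pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
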