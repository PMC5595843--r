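Package: tiltcsf
Title: V1 Population Modelling of Tilt Repulsion and Contrast Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A conductance-based model of a V1 orientation hypercolumn with
    centre-surround lateral inhibition, used to predict two monocular
    psychophysical measures from a shared set of network parameters: the
    centre-surround tilt illusion (via vector-average decoding of population
    activity) and the contrast sensitivity function (via signal detection
    theory on the most sensitive contrast channel). Includes ad-hoc
    psychometric fitting for 2D contrast-detection surfaces and per-surround
    orientation-discrimination functions with a three-key response design,
    weighted up-down adaptive staircase simulation, simulated observers with
    known ground truth, and a two-stage maximum-likelihood pipeline that fits
    the tilt data first (inhibition strength and orientation tuning width) and
    then the contrast data (neuronal sensitivity envelope) with the inhibition
    strength held fixed.
License: MIT
Encoding: UTF-8
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
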