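Package: aortawave
Title: Aortic Shape Modelling and Wave Haemodynamics After Coarctation Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical shape modelling of aortic centrelines with separate
    principal component analyses of 3D curvature and calibre, non-invasive
    central haemodynamics from flow and area waveforms (central systolic
    pressure by exponential pressure-area calibration, total arterial
    compliance by two-element windkessel tuning, and flow-area wave intensity
    analysis), association statistics between shape and haemodynamic load, and
    a one-dimensional arterial pulse-wave simulator with a time-varying
    elastance heart for in-silico proto-aorta experiments. Includes a synthetic
    cohort generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
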