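Package: thermovitals
Title: Contactless Vital-Sign Extraction from Radiometric Infrared Thermography Video
Version: 0.1.0
Authors@R:
    person("Thermovitals", "Maintainers", email = "maintainers@thermovitals.org",
           role = c("aut", "cre"))
Description: Tools for extracting vital signs from radiometric thermal video of
    bedridden patients: respiratory rate from dense optical-flow chest motion
    (polynomial-expansion flow, temporal filtering, Butterworth bandpass,
    autocorrelation peak picking), body-surface temperature trends from the head
    region with ambient-drift correction, and clinician-attendance profiles from
    per-frame bounding boxes. Includes bounding-box detection metrics (IoU,
    mAP@0.5, F1, coverage), Bland-Altman agreement statistics, readers/writers
    for a portable radiometric frame dialect (16-bit multi-page TIFF or CSV
    stacks) and darknet-style label files, and a seeded synthetic thermal-scene
    generator with exact ground truth so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
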