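Package: camvol
Title: Pulmonary Nodule Volumetry from Chest Radiograph Probability Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates three-dimensional pulmonary nodule volume from the
    two-dimensional class-activation probability maps that deep-learning
    nodule detectors produce for chest radiographs. Thresholds probability
    maps at a fixed cutoff, extracts up to three regions of interest per
    image with their area, weighted opacity-area product and probability
    statistics, fits polynomial regression models of degrees 1, 1.5 and 2
    (univariable area, or area plus mean probability) against reference CT
    volumes, ships the published fitted models as frozen constants, and
    classifies interval change (increased / decreased / no change) of
    nodules across serial radiographs. A calibrated synthetic-cohort
    generator reproduces the cohort structure and correlation pattern the
    method assumes, so the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    png,
    readr,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
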