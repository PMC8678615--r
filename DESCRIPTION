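Package: plotgrid
Title: Microplot Localization in UAV Orthomosaics by Hierarchical
    Grid-to-Image Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes crop breeding-trial microplots in UAV orthomosaic
    imagery by overlaying a known to-scale field map and refining its
    position hierarchically: per block, per column, and per microplot,
    maximizing vegetation-index overlap under layout constraints with a
    differential-evolution optimizer.  Includes vegetation-index
    preprocessing (Excess Green, NDVI), Pascal VOC annotation I/O,
    segmentation and detection metrics (Dice coefficient, displacement
    error, pixel-level confusion measures), differential-evolution weight
    tuning, and a synthetic orthomosaic generator with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
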