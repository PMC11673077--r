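Package: caliper3vv
Title: Vessel Diameters and the PA/Ao Ratio in the Fetal Three-Vessel View
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated biometry for fetal cardiac ultrasound screening from
    multi-class vascular segmentation masks of the three-vessel view (3VV).
    Extracts pulmonary artery (PA), ascending aorta (Ao) and superior vena
    cava (SVC) regions from label masks, measures vessel diameters as the
    maximal chord perpendicular to each region's principal axis, forms the
    PA/Ao ratio with outlier capping, derives cohort standard values
    (mean +/- 2 SD) and low/normal/high congenital heart disease grouping,
    and evaluates segmentation quality (Dice, mDice) and screening
    performance (deviation scores, ROC curves, AUC). Includes the bounded
    rotation and saturate-cast brightness/contrast training-data
    augmentation, detection-confidence 3VV frame selection from object
    detector output, a synthetic phantom generator (rasterized elliptical
    vessels with known geometry and configurable cohorts) so the whole chain
    is testable without clinical data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
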