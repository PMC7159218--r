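Package: tdlumetry
Title: Automated Morphometry of Terminal Duct Lobular Unit Involution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies terminal duct lobular unit (TDLU) involution from
    breast histopathology detections and segmentations. Computes five
    quantitative involution measures (TDLU density, median moment-ellipse
    span, median acini per TDLU, acini density, median TDLU area) with
    adipose-adjusted tissue area and calibration of automated acini counts
    to the manual counting scale, plus qualitative Russo lobule typing and
    Baer slide categories. Includes agreement statistics used to validate
    such pipelines (detection F1 with one-to-one matching, Dice, ICC(3,1)
    with confidence intervals, Fleiss' kappa), a synthetic-slide generator
    with exact ground truth, a deterministic reference segmentation backend
    for the synthetic renders, a trainable pixel-classifier backend, and
    readers/writers for masks, point detections, ASAP-style XML annotations
    and measure tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    igraph,
    xml2,
    yaml,
    jsonlite,
    png,
    tiff,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'slideModel.R'
    'agreement.R'
    'measures.R'
    'qualitative.R'
    'synthetic.R'
    'backends.R'
    'io.R'
    'pipeline.R'
    'tdlumetry-package.R'
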