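Package: perioStage
Title: Radiographic Bone Loss Measurement and Periodontitis Staging from
    Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures percentage radiographic bone loss (RBL) and assigns
    periodontitis stages (2017 World Workshop criteria, stages 1-3) from
    raster segmentation masks of dental radiographs. Given masks of the
    oral-cavity region enclosed by the periodontal bone levels, crown-band
    regions marking the cementoenamel junction (CEJ) level, and per-tooth
    instance masks, the package extracts per-column level curves, estimates
    each tooth's long axis by principal axes of inertia of its boundary
    pixels, intersects the axis with the bone and CEJ level curves, and
    converts the apex-to-intersection lengths into an RBL percentage and a
    stage. It also provides the matching evaluation suite (pixel accuracy,
    Dice, Jaccard, mean absolute stage difference, Pearson and intraclass
    correlation), a pluggable segmenter contract so a learned detector can
    supply the masks, and a synthetic two-jaw phantom generator with known
    ground truth so the whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'perioStage-package.R'
    'AllClasses.R'
    'utils.R'
    'polygon.R'
    'phantom.R'
    'perturb.R'
    'mask_io.R'
    'levels.R'
    'geometry.R'
    'staging.R'
    'evaluation.R'
    'segmenter.R'
    'config.R'
    'cli.R'
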