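Package: tpbsquant
Title: Automated Quantification of Three-Phase Bone Scintigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for automated quantification of planar three-phase bone
    scintigraphy (TPBS) of hands and feet. Generates synthetic phantom
    acquisitions with ground-truth region masks, trains small encoder-decoder
    (U-net style) segmentation networks with ensemble-based predictive-entropy
    uncertainty and an active-learning loop, validates segmentations with the
    Dice coefficient, and computes inverted-intensity ipsilateral/contralateral
    ratios per phase and anatomical region, including cut-off based cohort
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
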