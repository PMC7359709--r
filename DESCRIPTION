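Package: graftCT
Title: Thrombus and Lumen Morphometry on Vascular Grafts from MicroCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional physical characteristics of
    thrombus deposited on tubular vascular-graft biomaterials from X-ray
    microcomputed tomography (microCT) voxel volumes. Implements per-slice
    seeded intensity-range region growing with a partial-volume border-layer
    calibration, sequential multi-material labeling with a remainder rule for
    thrombus, per-slice cross-sectional area profiles, volume/length
    morphometry including a caliper-based cylindrical subtraction mode, a
    synthetic cylindrical graft phantom generator with exact ground truth for
    every contrast situation, and the validation statistics (through-origin
    linear fit with uncentered R-squared, per-group regression with an F-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
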