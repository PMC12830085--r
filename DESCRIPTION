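Package: octra
Title: Registration, Averaging, and Quantification for Cellular-Resolution
    Retinal OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for wavefront-sensorless adaptive-optics
    optical coherence tomography (OCT) of the mouse retina. Provides
    three-stage registration (rigid B-scan-plane alignment, sub-pixel en
    face phase correlation, per-B-scan axial alignment) with hierarchical
    batch averaging for speckle suppression; image-quality metrics
    (Tenengrad sharpness, local contrast, speckle contrast, SSIM, line
    profile correlation, one-phase exponential decay fits); a simulated
    sensorless Zernike modal optimization loop; seeded retinal layer
    segmentation with ganglion-cell-complex thickness maps; automated soma
    detection and longitudinal cell-loss quantification; and a synthetic
    retinal phantom generator with ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
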