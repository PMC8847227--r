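Package: hempspec
Title: Hyperspectral Image Analysis for Hemp Cultivar, Growth Stage and
    Organ Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for benchtop line-scan hyperspectral reflectance
    imaging of plant material: reading and writing ENVI-style datacubes,
    segmentation of plant samples and an in-scan grey reference panel via
    contrast-optimized normalized band difference images and intermodes
    histogram thresholding, extraction of reference-ratioed mean
    reflectance spectra, exploratory analysis (group mean spectra, PCA),
    and classification of cultivars, growth stages and plant organs by
    regularized linear discriminant analysis tuned by cross-validation
    and evaluated under repeated-holdout (Monte Carlo) validation with
    Fisher-LSD comparisons. Includes a synthetic scene and spectra
    generator emulating vegetation reflectance, uneven illumination and
    a flat 20% reference panel for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    lhs,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
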