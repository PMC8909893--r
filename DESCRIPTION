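Package: gingerHSI
Title: Hyperspectral Imaging Chemometrics for Pungent Constituent Ratios in
    Dried Ginger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for predicting the 6-gingerol to
    6-shogaol ratio of dried ginger powder from Vis-NIR hyperspectral
    images. Covers reflectance calibration of ENVI-format datacubes with
    white and dark reference frames, region-of-interest mean-spectrum
    extraction, spectral pre-treatments (SNV, MSC, moving-average filters,
    Savitzky-Golay derivatives), partial least squares regression fitted by
    NIPALS with leave-one-out latent-variable selection, LASSO regression by
    coordinate descent with cross-validated penalty selection,
    beta-coefficient and VIP wavelength selection, and model evaluation by
    R-squared, RMSE, RPD and limit of detection. A synthetic datacube
    generator with a Beer-Lambert-style forward model provides a fully
    reproducible test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    withr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
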