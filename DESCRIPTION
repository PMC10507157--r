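Package: sersvoc
Title: SERS Spectral Discrimination of Trace Gaseous Aldehydes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for surface-enhanced Raman
    scattering (SERS) discrimination of trace volatile aldehydes. Generates
    synthetic labelled SERS spectra for six aldehyde classes with shared
    4-aminothiophenol reporter bands and a phenylacetylene internal standard,
    performs internal-standard ratiometric calibration with limit-of-detection
    estimation, extracts 12 band-wise peak-position features, trains a small
    fully connected softmax classifier, and evaluates it with confusion
    matrices, one-vs-rest ROC curves and a PCA baseline. Also includes a 1D
    Fick diffusion model of analyte retention in a porous coating and the
    evanescent electromagnetic penetration-depth formula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
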