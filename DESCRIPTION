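Package: spectdose
Title: Quantitative SPECT, Partial-Volume Correction and Voxel Dosimetry
    for Radiopharmaceutical Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Digital-phantom simulation and quantitative analysis for
    radionuclide therapy imaging with I-131 SPECT/CT. Builds voxelized
    digital phantoms (uniform calibration cylinder, hot-sphere Jaszczak,
    anthropomorphic head-and-neck), simulates reconstructed count-rate
    images with system blur and Poisson noise, derives calibration
    factors and volume-dependent recovery coefficients, applies
    volume-based partial-volume corrections, integrates single-timepoint
    exponential decay to voxel absorbed dose with local-deposition and
    analytic photon-kernel engines, and propagates EANM-style activity
    uncertainty budgets (volume, calibration, recovery-coefficient,
    count-rate components and their covariance).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
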