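Package: arexcest
Title: Multi-Pool CEST Z-Spectrum Simulation, Lorentzian Fitting and AREX
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification of chemical exchange saturation
    transfer (CEST) MRI Z-spectra at preclinical field strength.  Provides a
    multi-pool Bloch-McConnell simulator for continuous-wave saturation,
    synthetic phantom and study generation with B0/B1 inhomogeneity and Rician
    noise, WASSR B0 mapping, double-angle B1 mapping, variable-TR T1 mapping,
    voxel-wise multi-pool Lorentzian background fitting, apparent
    exchange-dependent relaxation (AREX) metabolite mapping for glutamate,
    creatine and phosphocreatine, and a covariate-adjusted two-group
    statistics layer with false-discovery-rate control, effect sizes and
    partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
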