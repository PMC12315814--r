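Package: sersml
Title: Classification of Label-Free SERS Spectra of Extracellular Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for label-free surface-enhanced Raman
    spectroscopy (SERS) of extracellular vesicles: seeded synthetic spectrum
    simulation with Lorentzian bands, cosmic-ray despiking, morphologically
    weighted penalized least squares (MPLS) baseline correction, discrete
    Fourier transform smoothing, principal component analysis, a dual-form
    soft-margin support vector machine trained by sequential minimal
    optimization with Gaussian-process Bayesian hyperparameter search, a
    one-dimensional convolutional neural network trained with Adam,
    classification metrics (confusion matrix, recall, precision, ROC/AUC,
    cross-validated loss), Shapley-value and partial-dependence model
    interpretation, and SERS substrate quality metrics (enhancement factor,
    relative standard deviation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    jsonlite,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
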