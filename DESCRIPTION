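Package: pulsedecon
Title: Deconvolution of Pulmonary Vascular Remodeling Effects on
    Arterial Pressure and Impedance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-dimensional fluid-structure-interaction simulation of
    pulsatile blood flow on pulmonary arterial trees with a nonlinear
    anisotropic (Holzapfel-Ogden) vessel wall and three-element
    Windkessel outflow boundaries. Includes constitutive parameter
    estimation from uniaxial stress-strain data, frequency-domain
    impedance analysis (Z0, characteristic impedance), synthetic
    generators for vascular trees, wall-mechanics test data and
    right-ventricular inflow waveforms, and an in-silico scenario
    framework that separates the contributions of increased distal
    resistance, increased vessel stiffness and altered flow to
    main-pulmonary-artery pulse pressure and impedance in pulmonary
    hypertension.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
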