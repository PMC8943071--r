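Package: hrmmwi
Title: High-Resolution Millimeter-Wave Imaging Analysis of Skin Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ultra-wideband (12-110 GHz)
    millimeter-wave diagnostic imaging of skin lesions. Generates
    physics-informed synthetic scan cohorts from layered Debye skin phantoms,
    synthesizes two frequency sub-bands into a single ultra-wideband spectrum
    per scan position, reconstructs three-dimensional reflectivity cubes with
    dispersive frequency-domain back-propagation (with a delay-and-sum
    reference implementation), estimates penetration depth by two-region
    profile thresholding, extracts low-dimensional lesion features with a
    two-stage 3D principal component analysis, and evaluates
    benign-versus-malignant classifiers (LDA, KNN, linear and Gaussian SVM,
    MLP) over all principal-component subsets under leave-one-out
    cross-validation with ROC/AUC summaries, learning-curve extrapolation,
    and bootstrap ROC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    e1071,
    nnet,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
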