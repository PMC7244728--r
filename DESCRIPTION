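Package: wavefrontRx
Title: Predicting Subjective Refraction from Ocular Wavefront Aberrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting subjective sphero-cylindrical refraction from
    ocular wavefront aberrometry. Implements the LD/HD polynomial decomposition,
    in which higher-order modes carry no paraxial (degree <= 2) content, so the
    low-order coefficients alone encode the paraxial curvature-matching
    refraction. Provides power-vector (M, J0, J45) algebra, a seeded synthetic
    eye-cohort generator with a configurable mechanism by which higher-order
    aberrations shift the subjective endpoint, gradient-boosted-tree predictors
    with additive (SHAP) feature attribution, and the agreement and comparison
    statistics used to evaluate objective-refraction methods (accuracy,
    precision, Wilcoxon/Levene comparisons, Bland-Altman, confidence ellipses).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xgboost,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
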