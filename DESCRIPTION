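Package: cardiotrial
Title: Population-of-Models In Silico Cardiac Drug Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-scale pipeline for in silico proarrhythmia assessment on a
    reduced human ventricular cardiomyocyte model. Provides population-of-models
    generation and biomarker calibration, Hill-equation channel-block and
    dose-dependent enhancement pharmacology, detectors for early
    afterdepolarizations, repolarization failure and calcium-transient
    alternans, torsadogenic risk scoring with concentration-weighted
    aggregation, drug-description consistency checking against known
    phenotypes, disease-variant protocols (long QT syndrome type 2 and type 2
    diabetes remodeling) with arrhythmia-threshold searches, and an optional
    Nav1.8 sodium current with right-shifted gating.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    lhs,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
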