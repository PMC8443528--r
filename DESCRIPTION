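Package: tmshift
Title: Melting-Temperature Change upon Point Mutation: Dataset Analysis and Baseline Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing datasets of protein melting-temperature
    change (dTm) upon single point mutation and for fitting baseline dTm
    predictors from simple structure-derived features. Includes dataset
    loading and validation, substitution-matrix and binned-profile
    descriptive statistics, per-residue structural featurization (relative
    solvent accessibility, mean C/N/O B-factor, ternary secondary-structure
    code), a 19-input single-hidden-layer neural baseline with mock
    wild-type augmentation and replicated train/validation/test splits, a
    full baseline prediction grid over structural-feature combinations,
    per-substitution multiple linear regression, a forward/reverse mutation
    symmetry experiment, and a synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
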