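Package: storyEncoding
Title: Voxelwise Encoding Models and Concatenated Searchlight Decoding for
    Naturalistic Story Reading fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts voxelwise fMRI time series from time-varying story
    feature annotations via nonparametric per-feature temporal response
    signatures (finite-impulse-response lags) estimated with per-voxel
    ridge regression, and evaluates the fitted models by cross-validated
    two-alternative passage classification on group-concatenated data.
    Maps which feature sets are decodable where with a cross-subject
    concatenated searchlight, with permutation-based empirical null
    distributions and false-discovery-rate control. Includes a seeded
    synthetic-data generator (stories, ground-truth response signatures,
    multi-subject fMRI with AR(1) noise and anatomical jitter) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
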