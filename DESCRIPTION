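Package: voicelight
Title: Searchlight Decoding of Speaker Identity from fMRI with Permutation Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-voxel pattern analysis of speaker
    identity in event-related fMRI: single-trial beta-series estimation by
    ordinary least squares with a canonical double-gamma HRF and discrete
    cosine high-pass basis; whole-brain searchlight decoding with one-vs-one
    linear support vector machines under leave-one-run-out and
    leave-one-word-out cross-validation; nonparametric group inference by
    sign-flip permutation and single-covariate permutation regression with
    voxel-level family-wise error control via the maximum statistic; and
    behavioural analytics (percent correct, 3 x 3 confusion matrices,
    confusion-matrix rank correlations). A synthetic-data module generates
    multi-subject phantom cohorts with the design and statistical structure
    the analysis assumes, so every stage is verifiable without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
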