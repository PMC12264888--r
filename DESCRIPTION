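Package: lesionpls
Title: Multimodal Partial Least Squares Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent-variable lesion-symptom mapping for multimodal
    neuroimaging cohorts. Fits modality-specific partial least squares
    regression (PLSR) models relating region-level brain features to
    correlated language subtest scores, ranks features by variable
    importance in projection (VIP), validates predictions with
    leave-one-out cross-validation, and dissociates anatomy shared across
    subtests from anatomy uniquely tied to a single subtest via
    cross-modality VIP consensus and beta-threshold calling. Includes a
    calibrated synthetic multimodal cohort generator with planted shared
    and unique regional effects so the whole pipeline is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    MASS,
    data.table,
    jsonlite,
    pracma,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    knitr
Config/testthat/edition: 3
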