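Package: neckpose
Title: Posture Feature Extraction and Neck-Pain Classification from 2D Pose Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying non-specific neck pain from
    2D pose-estimation output recorded while subjects use a computer.
    Provides frame-level quality control (missing-value removal and
    per-keypoint Tukey-fence confidence filtering), personal-baseline
    calibration from the first 10 seconds of upright sitting, a
    381-feature posture schema (original, offset, status, neck-normalized
    and variation features over four task windows plus clinical
    covariates), dual feature selection (Mann-Whitney U test and the
    Lasso), repeated stratified nested cross-validation of ensemble
    classifiers including bagged random forests, and a synthetic
    case/control cohort generator with planted, recoverable effects for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    xgboost,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
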