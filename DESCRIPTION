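Package: crcval
Title: External Validation of Colorectal Cancer Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for externally validating published colorectal
    cancer (CRC) risk prediction models in prospective cohort data. Risk
    scores (logistic, Cox, and integer point systems) are encoded as
    declarative specification files and evaluated against a canonical
    cohort schema. The package computes discrimination (empirical AUC
    with DeLong variance, paired DeLong tests against an age-threshold
    comparator, Harrell's concordance for time-to-event data, subgroup
    analyses by sex, age, urbanicity and anatomical site), top-decile
    screening utility (sensitivity, specificity, predictive values),
    and decile-based calibration with affine recalibration of absolute
    risks. A synthetic cohort generator with a proportional-hazards
    outcome process, competing mortality, loss to follow-up and
    10-year administrative censoring provides ground-truth data for
    parameter-recovery testing, so the full pipeline runs without
    access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
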