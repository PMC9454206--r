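# Risk model specification. Structure follows Hong et al. 2017, a
# Korean logistic model (age, sex, smoking, alcohol, aspirin use) with
# published absolute risk. Missing aspirin use (outside the
# coronary-heart-disease subgroup) is imputed as non-use; the pipeline
# can drop the term instead. Coefficients are SYNTHETIC placeholders,
# not transcribed.
name: hong
model_type: logistic
native_horizon_years: 10
applicable_sex: both
intercept_or_baseline: -9.5
provenance: >-
  Structure after Hong et al. 2017 (Korean cohort, both sexes, logistic
  regression with absolute risk). Coefficients are synthetic
  placeholders.
variables:
  - name: age
    source_column: age
    kind: continuous
    coef: 0.080
    missing_policy: exclude_record
  - name: sex_male
    source_column: sex
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [female], contribution: 0.0, reference: true}
      - {values: [male], contribution: 0.40}
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [ex_regular], contribution: 0.20}
      - {values: [current], contribution: 0.50}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 0.30
    missing_policy: reference_level
  - name: aspirin
    source_column: aspirin_use
    kind: binary
    coef: -0.35
    missing_policy: {impute_value: false}
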