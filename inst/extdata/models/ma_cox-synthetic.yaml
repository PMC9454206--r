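# Risk model specification. The Ma et al. 2010 article also published a
# regression-based score on the same male Japanese cohort (age, BMI,
# smoking, alcohol, physical activity) without an absolute-risk
# estimate, so this spec yields a relative linear predictor only
# (no intercept). Coefficients are SYNTHETIC placeholders.
name: ma_cox
model_type: logistic
native_horizon_years: 10
applicable_sex: male
intercept_or_baseline: ~
provenance: >-
  Structure after the Ma et al. 2010 regression model (male Japanese
  cohort; relative score, no published absolute risk). Coefficients are
  synthetic placeholders.
variables:
  - name: age
    source_column: age
    kind: continuous
    coef: 0.070
    transform: {scale: 1, offset: -50}
    missing_policy: exclude_record
  - name: bmi
    source_column: bmi
    kind: continuous
    coef: 0.030
    transform: {scale: 1, offset: -23}
    missing_policy: exclude_record
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [ex_regular], contribution: 0.20}
      - {values: [current], contribution: 0.40}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 0.25
    missing_policy: reference_level
  - name: physical_activity
    source_column: physical_activity
    kind: continuous
    coef: -0.012
    missing_policy: reference_level
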