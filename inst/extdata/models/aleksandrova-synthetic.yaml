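# Risk model specification. Structure follows Aleksandrova et al. 2021,
# a large European-cohort logistic model (age, smoking, alcohol,
# physical activity, waist circumference, body height, vegetable,
# dairy, processed meat, and sugar/confectionery intake) published as a
# relative score without absolute risk. Coefficients are SYNTHETIC
# placeholders, not transcribed.
name: aleksandrova
model_type: logistic
native_horizon_years: 10
applicable_sex: both
intercept_or_baseline: ~
provenance: >-
  Structure after Aleksandrova et al. 2021 (European cohort, both
  sexes; relative score, no published absolute risk). Coefficients are
  synthetic placeholders.
variables:
  - name: age
    source_column: age
    kind: continuous
    coef: 0.065
    transform: {scale: 1, offset: -55}
    missing_policy: exclude_record
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [ex_regular], contribution: 0.15}
      - {values: [current], contribution: 0.35}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 0.20
    missing_policy: reference_level
  - name: physical_activity
    source_column: physical_activity
    kind: continuous
    coef: -0.010
    missing_policy: reference_level
  - name: waist
    source_column: waist_cm
    kind: continuous
    coef: 0.015
    transform: {scale: 1, offset: -85}
    missing_policy: reference_level
  - name: height
    source_column: height_cm
    kind: continuous
    coef: 0.010
    transform: {scale: 1, offset: -160}
    missing_policy: reference_level
  - name: vegetables
    source_column: vegetable_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [monthly], contribution: 0.0}
      - {values: [weekly], contribution: -0.05}
      - {values: [daily], contribution: -0.15}
  - name: dairy
    source_column: dairy_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [monthly], contribution: 0.0}
      - {values: [weekly], contribution: -0.05}
      - {values: [daily], contribution: -0.10}
  - name: processed_meat
    source_column: processed_meat_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [monthly], contribution: 0.05}
      - {values: [weekly], contribution: 0.15}
      - {values: [daily], contribution: 0.30}
  - name: sugar_confectionery
    source_column: sugar_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [monthly], contribution: 0.0}
      - {values: [weekly], contribution: 0.05}
      - {values: [daily], contribution: 0.10}
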