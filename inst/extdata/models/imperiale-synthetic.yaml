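# Risk model specification. Structure follows Imperiale et al. 2021, a
# US logistic model (age, sex, smoking, alcohol, physical activity,
# marriage, education, NSAID use, metabolic syndrome, red meat, aspirin
# use) with published absolute risk. The aspirin input is observable
# only in the coronary-heart-disease subgroup of the cohort schema;
# missing use is imputed as non-use (the pipeline can drop the term
# instead). Coefficients are SYNTHETIC placeholders, not transcribed.
name: imperiale
model_type: logistic
native_horizon_years: 10
applicable_sex: both
intercept_or_baseline: -5.8
provenance: >-
  Structure after Imperiale et al. 2021 (US cohort, both sexes,
  logistic regression with absolute risk). Coefficients are synthetic
  placeholders.
variables:
  - name: age
    source_column: age
    kind: continuous
    coef: 0.060
    transform: {scale: 1, offset: -45}
    missing_policy: exclude_record
  - name: sex_male
    source_column: sex
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [female], contribution: 0.0, reference: true}
      - {values: [male], contribution: 0.35}
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [ex_regular], contribution: 0.20}
      - {values: [current], contribution: 0.35}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 0.15
    missing_policy: reference_level
  - name: physical_activity
    source_column: physical_activity
    kind: continuous
    coef: -0.010
    transform: {scale: 1, offset: -20}
    missing_policy: reference_level
  - name: marital
    source_column: marital_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [married], contribution: 0.0, reference: true}
      - {values: [not_married], contribution: 0.10}
  - name: education
    source_column: education
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [high_school], contribution: 0.0, reference: true}
      - {values: [tertiary], contribution: 0.0}
      - {values: [middle], contribution: 0.05}
      - {values: [primary], contribution: 0.10}
      - {values: [none], contribution: 0.20}
  - name: nsaid
    source_column: nsaid_use
    kind: binary
    coef: -0.25
    missing_policy: reference_level
  - name: metabolic_syndrome
    source_column: metabolic_syndrome
    kind: binary
    coef: 0.20
    missing_policy: reference_level
  - name: red_meat
    source_column: red_meat_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [monthly], contribution: 0.05}
      - {values: [weekly], contribution: 0.10}
      - {values: [daily], contribution: 0.20}
  - name: aspirin
    source_column: aspirin_use
    kind: binary
    coef: -0.30
    missing_policy: {impute_value: false}
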