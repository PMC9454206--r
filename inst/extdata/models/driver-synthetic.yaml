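# Risk model specification. Structure (model type, variables, sex
# restriction, 20-year native horizon, published absolute risk) follows
# Driver et al. 2007, a US male-cohort logistic model for colorectal
# cancer. Coefficient values are SYNTHETIC placeholders with plausible
# effect directions/magnitudes, not transcribed from the source article.
name: driver
model_type: logistic
native_horizon_years: 20
applicable_sex: male
intercept_or_baseline: -6.2
provenance: >-
  Structure after Driver et al. 2007 (male US cohort, logistic
  regression, 20-year risk; age, BMI, smoking, alcohol). Coefficients
  are synthetic placeholders.
variables:
  - name: age_band
    source_column: age
    kind: categorical
    domain: [30, 80]
    missing_policy: exclude_record
    levels:
      - {range: [30, 50], contribution: 0.0, reference: true}
      - {range: [50, 60], contribution: 0.90}
      - {range: [60, 70], contribution: 1.50}
      - {range: [70, .inf], contribution: 1.90}
  - name: bmi_band
    source_column: bmi
    kind: categorical
    domain: [0, 100]
    missing_policy: exclude_record
    levels:
      - {range: [0, 25], contribution: 0.0, reference: true}
      - {range: [25, 30], contribution: 0.15}
      - {range: [30, .inf], contribution: 0.30}
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0.0, reference: true}
      - {values: [ex_regular], contribution: 0.25}
      - {values: [current], contribution: 0.45}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 0.20
    missing_policy: reference_level
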