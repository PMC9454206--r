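# Risk model specification. Structure follows the Ma et al. 2010 point
# score (male Japanese cohort, 10-year risk; age, BMI, smoking, alcohol,
# physical activity; published points-to-absolute-risk table). Point
# values and risks are SYNTHETIC placeholders, not transcribed.
name: ma_point
model_type: points
native_horizon_years: 10
applicable_sex: male
provenance: >-
  Structure after Ma et al. 2010 point score (male Japanese cohort,
  10-year risk with published absolute-risk strata). Points and risk
  table are synthetic placeholders.
variables:
  - name: age_band
    source_column: age
    kind: categorical
    domain: [30, 80]
    missing_policy: exclude_record
    levels:
      - {range: [30, 50], contribution: 0, reference: true}
      - {range: [50, 60], contribution: 2}
      - {range: [60, 70], contribution: 4}
      - {range: [70, .inf], contribution: 5}
  - name: bmi_band
    source_column: bmi
    kind: categorical
    domain: [0, 100]
    missing_policy: exclude_record
    levels:
      - {range: [0, 25], contribution: 0, reference: true}
      - {range: [25, .inf], contribution: 1}
  - name: smoking
    source_column: smoking_status
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0, reference: true}
      - {values: [ex_regular], contribution: 1}
      - {values: [current], contribution: 2}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 1
    missing_policy: reference_level
  - name: physical_activity_band
    source_column: physical_activity
    kind: categorical
    domain: [0, .inf]
    missing_policy: reference_level
    levels:
      - {range: [20, .inf], contribution: 0, reference: true}
      - {range: [0, 20], contribution: 1}
risk_table:
  - {min: 0, max: 1, risk: 0.0010}
  - {min: 2, max: 3, risk: 0.0022}
  - {min: 4, max: 5, risk: 0.0042}
  - {min: 6, max: 7, risk: 0.0075}
  - {min: 8, max: 10, risk: 0.0125}
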