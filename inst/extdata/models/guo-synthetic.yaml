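# Risk model specification. Structure follows Guo et al. 2020, a point
# score developed in a male Chinese cohort (age, alcohol, diabetes,
# waist circumference, occupational sitting time; published absolute
# risks). The sitting-time input maps to the cohort's occupational
# sitting category, a proxy declared at spec level. Points and risks
# are SYNTHETIC placeholders, not transcribed.
name: guo
model_type: points
native_horizon_years: 10
applicable_sex: male
provenance: >-
  Structure after Guo et al. 2020 point score (male Chinese cohort,
  10-year risk with published absolute-risk strata; sitting time via
  occupational-category proxy). Points and risk table are synthetic
  placeholders.
variables:
  - name: age_band
    source_column: age
    kind: categorical
    domain: [30, 80]
    missing_policy: exclude_record
    levels:
      - {range: [30, 50], contribution: 0, reference: true}
      - {range: [50, 60], contribution: 1}
      - {range: [60, 70], contribution: 2}
      - {range: [70, .inf], contribution: 3}
  - name: alcohol
    source_column: alcohol_weekly
    kind: binary
    coef: 1
    missing_policy: reference_level
  - name: diabetes
    source_column: diabetes
    kind: binary
    coef: 2
    missing_policy: reference_level
  - name: waist_band
    source_column: waist_cm
    kind: categorical
    domain: [0, 300]
    missing_policy: reference_level
    levels:
      - {range: [0, 85], contribution: 0, reference: true}
      - {range: [85, 95], contribution: 1}
      - {range: [95, .inf], contribution: 2}
  - name: sitting_time
    source_column: sitting_time
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [low], contribution: 0, reference: true}
      - {values: [medium], contribution: 0}
      - {values: [high], contribution: 1}
risk_table:
  - {min: 0, max: 1, risk: 0.0018}
  - {min: 2, max: 3, risk: 0.0038}
  - {min: 4, max: 5, risk: 0.0070}
  - {min: 6, max: 9, risk: 0.0120}
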