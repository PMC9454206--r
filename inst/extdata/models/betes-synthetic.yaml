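# Risk model specification. Structure follows Betes et al. 2003, a
# Spanish point score (age, sex, BMI) without published absolute risks.
# Points are SYNTHETIC placeholders, not transcribed.
name: betes
model_type: points
native_horizon_years: 10
applicable_sex: both
provenance: >-
  Structure after Betes et al. 2003 point score (Spanish cohort, both
  sexes; no published absolute risk). Points are synthetic placeholders.
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
  - name: sex_male
    source_column: sex
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [female], contribution: 0, reference: true}
      - {values: [male], contribution: 1}
  - name: bmi_band
    source_column: bmi
    kind: categorical
    domain: [0, 100]
    missing_policy: exclude_record
    levels:
      - {range: [0, 25], contribution: 0, reference: true}
      - {range: [25, .inf], contribution: 1}
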