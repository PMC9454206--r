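# Risk model specification. Structure follows Chen et al. 2014, a small
# Chinese-cohort point score for advanced neoplasia/CRC (age, sex,
# coronary-heart-disease history, egg intake, defecation frequency)
# without published absolute risks. Points are SYNTHETIC placeholders.
name: chen
model_type: points
native_horizon_years: 10
applicable_sex: both
provenance: >-
  Structure after Chen et al. 2014 point score (Chinese cohort, both
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
  - name: chd_history
    source_column: chd_history
    kind: binary
    coef: 1
    missing_policy: reference_level
  - name: egg_intake
    source_column: egg_freq
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [never], contribution: 0, reference: true}
      - {values: [monthly], contribution: 0}
      - {values: [weekly], contribution: 0}
      - {values: [daily], contribution: 1}
  - name: defecation_frequency
    source_column: defecation_frequency
    kind: categorical
    missing_policy: reference_level
    levels:
      - {values: [daily], contribution: 0, reference: true}
      - {values: [lt_daily], contribution: 1}
      - {values: [gt_daily], contribution: 1}
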