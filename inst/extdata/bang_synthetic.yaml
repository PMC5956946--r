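# SYNTHETIC example of an ordinal-points diabetes risk test (ADA-style
# questionnaire scoring).  Bin boundaries and points are illustrative
# placeholders, NOT the published instrument; replace with the published
# rules before substantive use.  Ordinal scores are not Z-standardized.
name: bang_synthetic
outcome_family: ordinal_points
stratify_by: null
standardize: false
points:
  all:
    - {covariate: age, breaks: [40, 50, 60], points: [0, 1, 2, 3]}
    - {covariate: bmi, breaks: [25, 30, 40], points: [0, 1, 2, 3]}
    - {covariate: sbp, breaks: [120, 140], points: [0, 1, 2]}
    - {covariate: family_history_diabetes, if_true: 1}
    - {covariate: smoking, if_true: 1}
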