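# SYNTHETIC example of a sex- and race-specific 10-year atherosclerotic
# CVD risk equation (Cox-type).  Placeholder coefficients with realistic
# magnitudes, NOT the published pooled cohort equations; replace with
# coefficients sourced from the original publication.
name: ascvd_synthetic
outcome_family: survival10y
stratify_by: subgroup
standardize: true
terms:
  white_man: &terms
    - {covariate: age, transform: identity, coefficient: 0.065}
    - {covariate: sbp, transform: identity, coefficient: 0.018}
    - {covariate: total_chol, transform: identity, coefficient: 0.008}
    - {covariate: hdl, transform: identity, coefficient: -0.025}
    - {covariate: smoking, transform: identity, coefficient: 0.55}
    - {covariate: glucose, transform: identity, coefficient: 0.012}
  white_woman: *terms
  black_man: *terms
  black_woman: *terms
s0:
  white_man: 0.88
  white_woman: 0.96
  black_man: 0.93
  black_woman: 0.96
lp_mean:
  white_man: 7.6256
  white_woman: 7.0675
  black_man: 7.2922
  black_woman: 7.0192
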