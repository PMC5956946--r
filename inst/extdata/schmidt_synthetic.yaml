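# SYNTHETIC example of a logistic diabetes risk equation fitted on
# clinical covariates.  Placeholder coefficients with realistic
# magnitudes, NOT the published equation; replace with coefficients
# sourced from the original publication.
name: schmidt_synthetic
outcome_family: logistic
stratify_by: null
standardize: true
terms:
  all:
    - {covariate: age, transform: identity, coefficient: 0.035}
    - {covariate: waist, transform: identity, coefficient: 0.045}
    - {covariate: sbp, transform: identity, coefficient: 0.012}
    - {covariate: glucose, transform: identity, coefficient: 0.055}
    - {covariate: family_history_diabetes, transform: identity, coefficient: 0.6}
    - {covariate: hdl, transform: identity, coefficient: -0.02}
intercept:
  all: -14.7901
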