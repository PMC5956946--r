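# SYNTHETIC example of a sex-specific 10-year general CVD risk equation
# (Cox-type: risk = 1 - S0 ^ exp(LP - lp_mean)).  Coefficient values here
# are illustrative placeholders with realistic magnitudes, NOT the
# published equation; replace them with coefficients sourced from the
# original publication before any substantive use.
name: framingham_synthetic
outcome_family: survival10y
stratify_by: sex
standardize: true
terms:
  man:
    - {covariate: age, transform: log, coefficient: 3.0}
    - {covariate: total_chol, transform: log, coefficient: 1.1}
    - {covariate: hdl, transform: log, coefficient: -0.9}
    - {covariate: sbp, transform: log, coefficient: 1.9}
    - {covariate: smoking, transform: identity, coefficient: 0.65}
  woman:
    - {covariate: age, transform: log, coefficient: 2.3}
    - {covariate: total_chol, transform: log, coefficient: 1.2}
    - {covariate: hdl, transform: log, coefficient: -0.7}
    - {covariate: sbp, transform: log, coefficient: 2.8}
    - {covariate: smoking, transform: identity, coefficient: 0.52}
s0:
  man: 0.88
  woman: 0.95
lp_mean:
  man: 23.6315
  woman: 26.1345
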