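---
title: "Methods: quantifying the added value of a MetS severity score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the added value of a MetS severity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the synthetic-data
generator, the numerical choices, and the judgement calls behind
`metsadd`. The worked numbers in the README come from the drivers in
`analysis/`; everything here is about *why* the computations are set up
the way they are.

## 1. The question and the model

The substantive question is incremental value: given an established
10-year risk score $S$ for coronary heart disease (CHD) or type 2
diabetes (T2DM), does a continuous metabolic-syndrome severity score
$M$ improve prediction? Four nested models per comparator, all adjusted
for study site as a fixed effect:

$$
\begin{aligned}
\text{A:}&\; g(\lambda \text{ or } p) = \beta_S S \\
\text{B:}&\; \beta_M M \\
\text{C:}&\; \beta_S S + \beta_M M \\
\text{D:}&\; \beta_S S + \beta_M M + \beta_{SM}\, S M
\end{aligned}
$$

CHD uses Cox proportional hazards on day-resolution follow-up; T2DM uses
logistic regression on a dichotomous 10-year incidence indicator,
because T2DM onset is interval-censored by the visit schedule and a
precise event day is not observable. Added value is read off four
complementary statistics, each authored in this package and tested
against exhaustive brute-force oracles:

- **c-statistic.** Binary outcomes: the all-pairs concordance
  probability with ties counted 1/2, standard error by the
  placement-value (DeLong) method. Survival outcomes: a Harrell-type
  concordance restricted to the horizon — usable pairs are
  $(i, j)$ with $t_i < t_j$, subject $i$ an event, and
  $t_i \le h$.
- **IDI.** Difference in discrimination slopes
  $(\bar p_{\text{events}} - \bar p_{\text{non-events}})$ between the
  new and old model; its standard error is computed from the paired
  per-subject differences.
- **Continuous NRI.** Event component: proportion of events whose risk
  rose minus proportion whose risk fell; non-event component with signs
  reversed; ties count neither; the overall NRI is exactly their sum.
- **AIC** as $2k - 2\log L$, and **VIF** ($1/(1-R^2)$, flagged severe
  above 10) for the Model C design, to verify that $S$ and $M$ are not
  simply collinear.

### Survival extensions at the horizon

With censoring before the 10-year horizon $h = 3652$ days, "event by
$h$" is not observed for everyone, so the binary IDI/NRI need
extensions:

- **NRI**: participants are grouped by the *direction* of the risk
  change (up/down/tied); within each group the event probability by $h$
  is the Kaplan–Meier estimate; the event NRI is
  $[P(\text{up})\hat p_{\text{up}} - P(\text{down})\hat p_{\text{down}}]/\hat p$,
  and analogously for non-events.
- **IDI**: each subject contributes a fractional event weight $w_i$
  — 1 if an event by $h$, 0 if followed beyond $h$ event-free, and
  $1 - S(h)/S(c_i)$ (the conditional KM event probability) if censored
  at $c_i < h$ — and the discrimination slopes are $w$-weighted means.

Both constructions reduce *exactly* (to machine precision, asserted in
the tests) to the binary statistics when no one is censored before the
horizon. A `complete_case` fallback (drop pre-horizon censored subjects)
is provided; the test suite includes a scenario with risk-dependent
early dropout where the two estimators diverge in the direction the
censoring mechanism predicts.

## 2. The MetS severity score

The severity score is the first (only) factor of a maximum-likelihood
one-factor confirmatory factor analysis (`stats::factanal`) of waist
circumference, log triglycerides, HDL, systolic blood pressure, and
fasting glucose, fitted separately in each of the four sex-by-race
subgroups and standardized so each reference subgroup scores to mean 0,
SD 1. Choices:

- **Log triglycerides.** Triglycerides are strongly right-skewed and
  generated log-normally; the factor model assumes approximate
  normality, so they enter on the log scale. The other components enter
  untransformed.
- **Sign convention.** Loadings are flipped, if necessary, so glucose
  loads positively (higher score = worse metabolic state); HDL then
  loads negatively, as it should.
- **Degeneracy guard.** A fit is flagged `degenerate` when fewer than
  two absolute loadings reach 0.15. This catches both "no common
  factor" and Heywood-type solutions where a single variable absorbs
  the factor; degenerate equations refuse to score.
- **Small subgroups.** Below 200 complete cases a subgroup-specific
  factanal is unstable; `score_mets_cohort()` falls back to the pooled
  (all-subgroup) equation and says so. The default cohort size never
  triggers this; small demonstration cohorts do.

HOMA-IR is included as `insulin × glucose / 405` for descriptive use.

## 3. The synthetic cohort generator

No individual-level data are redistributed; the generator produces a
cohort with the structure the analysis needs.

- **Latent structure.** One standard-normal factor $f_i$ per
  participant; component $k$ is
  $\mu_{gk} + \sigma_{gk}(\lambda_k f_i + \sqrt{1-\lambda_k^2}\,\varepsilon)$
  within subgroup $g$, with default loadings
  $(0.70, 0.60, -0.50, 0.50, 0.60)$ for (waist, log-TG, HDL, SBP,
  glucose). Triglycerides and insulin are moment-matched log-normals so
  their marginal means/SDs equal the configured values.
- **Default marginals** (means/SDs per subgroup, cohort size 13,141,
  subgroup mix, age distributions, five study sites) are fixed
  constants of the package chosen to resemble a pooled bi-ethnic
  mid-1990s US cohort; tests check simulated marginals against the
  config within Monte-Carlo error, not against external data.
- **CHD events** follow a Weibull proportional-hazards model (shape
  1.1, scale 30 years) with linear predictor = subgroup offset +
  weighted age/smoking/cholesterol/SBP terms + $0.35 \times$ true
  severity. The subgroup offsets were calibrated once, by root-finding
  on large Monte-Carlo runs, so subgroup 10-year incidences land near
  plausible published magnitudes (roughly 25/9/10/6 % across the four
  subgroups); they are frozen constants, not refit at run time.
- **T2DM** is generated as a Bernoulli draw from a logistic model
  (severity, glucose, BMI, age, family history; calibrated subgroup
  intercepts), then *detected* through the visit schedule: converters
  get a conversion day and post-conversion labs above threshold;
  non-converters' labs are capped just below every diagnostic
  threshold. Detection through the visit rules therefore equals the
  generative draw exactly — a property the tests assert — so outcome
  misclassification is deliberately absent from the generator.
- **Censoring**: administrative at 24 years plus exponential dropout
  (rate 0.0223/yr ≈ 20 % loss by 10 years). Times are rounded to whole
  days, which intentionally creates ties for the Efron handling and the
  tied-pair paths of the concordance code.
- **Visit rules.** ARIC-type sites: fasting glucose ≥ 126 mg/dL,
  non-fasting ≥ 200, medication, or self report (HbA1c ignored).
  JHS-type site: fasting ≥ 126, HbA1c ≥ 6.5 %, or medication (self
  report ignored). The 10-year window is a ≤ 3652-day boundary, tested
  at 3652 vs 3653 exactly.
- **Limits.** The generator is single-factor (no residual component
  correlations beyond the factor), has proportional hazards by
  construction, no competing-risk correlation between death and
  covariates, no measurement error, and no secular drift across visits.
  It is a test bed for the *statistics*, not an epidemiological
  emulator.

### Comparator scores

The four YAML files in `inst/extdata/` are *synthetic placeholders* in
three published-score shapes — Cox-type 10-year survival
($1 - S_0^{\exp(LP - \overline{LP})}$), logistic, and ordinal points
with left-closed bins — with coefficients chosen by us. The published
coefficient sets are not redistributed, but the declarative
`risk_score_spec` schema accepts them verbatim. Continuous scores are
Z-standardized in-sample for display (so effect sizes read "per SD");
ordinal point scores are not.

## 4. Numerical choices

- **Ties in Cox fits**: Efron by default (day-resolution times tie
  heavily); Breslow available and tested to agree when ties are absent.
  Convergence warnings are promoted to errors.
- **Quintile cuts**: empirical 20/40/60/80 % quantiles (type 7), values
  exactly at a boundary go to the *lower* quintile. Duplicate cut
  points (as happens for coarse ordinal scores) are flagged degenerate
  and the pipeline records the flag rather than estimating merged bins.
- **Baseline risk at a horizon**: Cox 10-year risks use the Breslow
  cumulative baseline hazard at the last event time ≤ horizon, with the
  linear predictor referenced to zero covariates.
- **Serialization**: YAML round trips write with `precision = 15`
  (default precision loses ~1e-8); JSON uses `digits = NA`.
- **Problem sizes**: oracle tests run at n ≤ 500 where $O(n^2)$
  enumeration is exact and fast; calibration/power properties use
  n = 2,000–10,000 with replicate counts chosen so the asserted bounds
  are ≥ 4 Monte-Carlo standard errors from their thresholds.

## 5. Judgement calls

- **Continuous vs quintile interaction**: both are reported. Model D's
  single product term is the powerful test under a linear trend; the
  per-quintile hazard ratios are the honest display when the added
  value is concentrated (e.g. in the lowest score quintile) without
  assuming linearity. The tests verify the quintile machinery localizes
  a quintile-1-only effect correctly.
- **In-sample evaluation.** c/IDI/NRI are computed on the fitting
  sample, as is conventional for incremental-value reporting; the
  optimism this induces is shared between nested models and is not
  corrected here. The acceptance tests therefore build their null
  calibration from outcome-independent prediction perturbations rather
  than in-sample refits, which are biased upward by construction.
- **T2DM as logistic, not interval-censored survival**: with 2–3 visits
  in 10 years, a parametric interval-censored model would lean heavily
  on distributional assumptions; the dichotomous 10-year indicator is
  the simpler estimand and matches how such outcomes are usually
  analysed. Participants with no usable follow-up visits are excluded
  (counted in the exclusion tally) rather than imputed.
- **Exclusion cascade order** (other race, baseline diabetes, baseline
  CHD, stroke, missing components, non-fasting, no T2DM follow-up) is
  fixed and first-filter counted, so the tally columns sum to
  input − analytic.
- **Significance conventions**: Wald tests and 1.96-SE intervals
  throughout; no multiplicity adjustment across the four comparators —
  the package reports per-comparison inference and leaves family-wise
  framing to the analyst.
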