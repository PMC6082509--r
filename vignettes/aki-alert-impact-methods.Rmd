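---
title: "Methods: creatinine-based AKI ascertainment and before-after impact analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: creatinine-based AKI ascertainment and before-after impact analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`akiimpact` implements the computational core of a controlled before-after
evaluation of acute kidney injury (AKI) alerting in acute medical
admissions: a synthetic two-site, two-period electronic-health-record
generator, serum-creatinine-based AKI ascertainment, risk-score alerting,
study inclusion rules, and the impact statistics (contingency-table odds
ratios and a clustered difference-in-differences logistic model). This
vignette records the models, the tunable parameters, and the design choices
made where more than one reading was defensible.

## AKI ascertainment

All detection uses serum creatinine (SCr, µmol/l) only; urine-output and
renal-replacement criteria are deliberately out of scope because acute
medical patients rarely have urinary catheters in place.

**Baseline.** The pre-admission baseline follows the national e-alert
convention: the lowest result in the 7 days before admission if any exists,
otherwise the median of results 8–365 days back, otherwise no baseline
(`derive_baseline()`). Both lookbacks are arguments.

**Community-acquired (CA) AKI** is present at admission when
$\mathrm{SCr}_{\mathrm{adm}} / \mathrm{baseline} \ge 1.5$, or when
$\mathrm{SCr}_{\mathrm{adm}} \ge 354$ µmol/l; without a baseline, CA-AKI is
assumed absent below that absolute level. All comparisons are inclusive
("$\ge$") at the printed thresholds — 1.5, 26.5 and 354 exactly at the
boundary trigger.

**Hospital-acquired (HA) AKI** is detected at the earliest measurement time
$t \le 168$ h with either

$$\frac{v(t)}{v(0)} \ge 1.5
  \quad\text{or}\quad
  v(t) - \min_{\,t-48 \le s \le t} v(s) \ge 26.5\ \mu\mathrm{mol/l},$$

where $v(0)$ is the first in-hospital measurement. Interpretation choices,
each of which the package fixes once:

* *Admission value* = first SCr at $t \ge 0$; the only unambiguous
  definition.
* The rolling window compares each value with the *minimum* over the
  trailing 48 h (including the admission value when in range) — the
  standard, sensitivity-maximising reading of a "rolling 48 hours".
* The 7-day horizon constrains the *triggering* measurement; later values
  still contribute to peak rise and staging, which are defined as maxima
  over the whole series.
* No interpolation: detection operates on observed measurements only.
* The 354 µmol/l absolute-level rule applies to CA ascertainment only.

**Staging** uses ratio bands on $r = \max_t v(t) / \text{reference}$
(baseline for CA, admission value for HA): stage 3 for $r \ge 3$, stage 2
for $2 \le r < 3$, stage 1 when detection fired but $r < 2$. One corner is
undefined by ratio bands: CA detected through the absolute level with no
baseline. The package stages it 3, since that absolute level is itself a
stage-3 criterion.

A note on monotonicity: detection is *not* monotone in single post-admission
values — raising an intermediate dip raises the 48-hour window minimum and
can remove an absolute-rise trigger. The properties that do hold, and that
the test suite asserts, are (i) scaling an entire series up never delays
onset, (ii) raising the value at one time only makes triggering at that time
easier, and (iii) ratio-rule detections survive any pointwise increase.

## Risk-score alerting

The prediction score is an additive integer score over admission-time
fields, supplied as a declarative weight table (predictor, comparator,
threshold, points) so any published weighting can be dropped in. The
packaged default, `aps_weights_synthetic.csv`, is a **synthetic stand-in**:
the validated score's exact weights are not reproduced here, so the default
uses the documented predictor families (age bands, chronic kidney disease,
heart failure, diabetes, liver disease, tachypnoea, reduced consciousness,
early warning score) with points calibrated once so that roughly a quarter
of simulated admissions reach the cut-off — the at-risk fraction the
alerting workflow was designed around. The cut-off defaults to 5 points,
chosen in the original workflow for specificity over sensitivity. Scores
are computed once at admission and never re-scored.

Alert states: RED for AKI (CA at admission, HA at onset), AMBER for an
at-risk score without AKI, GREEN otherwise. States only escalate. Bundle
compliance is reported as percentages of RED and of all flagged admissions
with a submitted complete bundle.

## Cohort rules

Included admissions: age ≥ 18, medical specialty, at least one night in
hospital, at least two SCr measurements, not moved directly from the
emergency department to intensive care. "At least one night" is
operationalised as discharge on a later *calendar day* than admission (a
23:00 admission discharged at 04:00 counts; a same-day 9-to-5 stay does
not). Admissions violating several rules carry the first matching reason in
the order: direct ED-to-ICU, under 18, non-medical, no overnight stay,
single SCr. Seven-day mortality is anchored at the admission timestamp;
length of stay runs to discharge or in-hospital death. HA-AKI incidence
denominators exclude CA-AKI admissions (at-risk population). The
single-admission subset counts a patient within a site across both periods;
cross-site identities are not linked, since sites are analysed separately.

## Impact statistics

Unadjusted before/after contrasts within each site are 2×2 tables (post vs
pre × event vs no event) with the odds ratio $(a/b)/(c/d)$, the Woolf
log-scale interval
$\exp\{\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d}\}$, and
Pearson's chi-square without continuity correction (cells are large
throughout; Yates is available as an option). Zero cells get the
Haldane–Anscombe +0.5 correction, flagged on the result. Stratified
categorical contrasts use the Cochran–Mantel–Haenszel chi-square in closed
form (the base-R implementation is the cross-check in tests but rejects
single-stratum arrays). Continuous contrasts use Welch's t or Mann–Whitney
U with the normal approximation and no continuity correction, so identical
samples give p = 1 under ties. No multiplicity adjustment is applied
anywhere; reported p-values are labelled unadjusted.

**Difference-in-differences.** The intervention effect is the site×period
interaction in

$$\operatorname{logit} P(Y=1) = \beta_0 + \beta_1\,\mathrm{site}
  + \beta_2\,\mathrm{period} + \beta_3\,(\mathrm{site}\times\mathrm{period})
  + \gamma^\top x,$$

with $x$ = age plus six comorbidity flags, fitted by generalised estimating
equations with an exchangeable working correlation and a cluster-robust
(sandwich) variance over patients, so repeated admissions of one patient do
not masquerade as independent information. The fitter is written in-package
(no GEE dependency is required): Fisher scoring on the GEE score equations,
with the exchangeable inverse $R^{-1} = (I - \gamma J)/(1-\alpha)$ reducing
every cluster sum to `rowsum()` calls — tens of thousands of clusters fit in
milliseconds, and with the independence structure the estimates coincide
exactly with `glm()` and the robust variance with the clustered HC0
sandwich (both tested). The binomial scale is fixed at 1 and $\alpha$ is
moment-estimated from Pearson residual cross-products, clamped to
$[0, 0.95]$. Convergence is declared at a maximum coefficient step below
$10^{-10}$; separation or non-convergence is surfaced as `fit_ok = FALSE`
with a warning rather than silently reported.

In the saturated unadjusted case with independent clusters the interaction
odds ratio equals the ratio of the two unadjusted site odds ratios exactly;
the test suite asserts this identity to floating-point tolerance on the
summary-derived data. Continuous outcomes (peak SCr rise, length of stay)
use a linear mixed model with a patient random intercept (`lme4`); a
singular fit — inevitable when every patient appears once — falls back to
ordinary least squares with a message, where it equals OLS by construction.
Inference is normal-approximation Wald throughout.

Covariate-adjusted interaction estimates from the original evaluation are
*not* reproducible from published summaries (they require the raw
patient-level records), so the adjusted model is validated by simulation
instead: interval coverage of a planted effect and type-I error under the
null, described next.

## The synthetic generator

`sim_config()` defaults encode the study conditions: ~7,500 admissions per
site-period cell (6,500 patients × 1.15 mean admissions), CA-AKI prevalence
8.3%, HA-AKI base rates 8.3% (intervention) / 6.5% (control) of non-CA
admissions, mortality 25% given HA-AKI, 21% given CA-AKI, 6.5% otherwise,
age ~ N(74.5, 17²) truncated to [18, 105], comorbidity prevalences from the
published case-mix table, log-normal length of stay with mean ≈ 11 days and
a heavy tail, and intervention effects applied only in the
intervention-site post period (defaults 0.91 on HA-AKI odds and 0.66 on
death-given-HA-AKI odds — the unadjusted post/pre odds-ratio contrasts the
published tables imply). Where the source gives no value the package fixes
one realistic choice: 20% of patients lack any baseline history; 4% of
admissions are planted to violate one inclusion rule; planted HA-AKI
severity falls in the stage-1/2/3 bands with probabilities 0.78/0.15/0.07.

Creatinine series are sampled at admission and then daily with ±5 h jitter
up to eight days or discharge. Unplanted values stay in a ±12 µmol/l band
around the admission value — by construction that band can never trigger
either detection rule (maximum in-window rise 24 < 26.5; ratio below 1.5
for any admission value above 24 µmol/l) — while planted HA trajectories
are flat until onset, jump to admission × severity at an inserted onset
measurement, and plateau. Planted CA admissions draw an admission value at
least 1.6× the true baseline while history jitter is within ±5%, so the
derived baseline can never blunt the ratio below 1.5; non-CA admissions cap
at 1.3× baseline, so the derived ratio never exceeds ≈ 1.37. Consequently
ascertainment recovers the planted classification *exactly* on included
admissions — a property the tests assert — which is what makes the
generator usable as ground truth for the estimator simulations.

What the generator does not emulate: integer-rounded laboratory reporting,
within-stay correlation of vitals, readmission-dependent case mix, seasonal
admission patterns, death-censored lab sampling (sampling runs to the
planned stay), or realistic ICD-10 coding noise. Passing tests therefore
demonstrate correctness of the *pipeline logic and estimators* under the
stated statistical structure, not performance on real hospital data.

Determinism: one seeded stream with vectorised draws in fixed order;
identical configuration and seed give byte-identical cohorts, and the
caller's RNG state is restored. We considered per-patient substreams (so
that enlarging a cohort leaves earlier patients unchanged) and rejected
them: seeding per patient costs seconds per replicate at study scale and
buys nothing for the properties tested here.

## Simulation sizes and what they show

The estimator validation uses 5,000 admissions per cell (the scale at which
each replicate carries roughly 1,200 HA-AKI cases, matching the study),
200 replicates per condition: with a planted mortality interaction OR of
0.7 the 95% interval covers the truth in ≥ 90% of replicates, and under the
null the rejection rate at α = 0.05 stays within [3%, 7%]. Detection is
checked against a brute-force all-pairs oracle on 10,000 random series with
zero discrepancies required. Smaller cohorts (300–2,000 patients per cell)
drive the unit and property tests. Early in-hospital deaths can precede the
first midnight and are then excluded by the overnight rule, exactly as the
study's inclusion criteria would do; the induced selection on
mortality-given-HA-AKI is identical across cells and shifts the interaction
OR by well under 1%, which the coverage results absorb.

## Known limitations

* The synthetic score weights are placeholders; discrimination of the
  packaged score is meaningless and deliberately untested.
* Adjusted DiD point estimates from the original evaluation are not
  reproducible from published summaries; only unadjusted quantities are
  checked exactly.
* The GEE implementation supports exchangeable and independence working
  correlations only — adequate for cluster sizes of one to a few
  admissions, not for long longitudinal series.
* Wald normal inference is used throughout; with very few clusters,
  small-sample corrections would be needed.
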