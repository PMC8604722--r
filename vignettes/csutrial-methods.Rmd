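---
title: "Simulating and analyzing a dose-ranging CSU trial"
author: "csutrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing a dose-ranging CSU trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csutrial)
```

# Scope

`csutrial` implements the complete analytic machinery of a randomized,
placebo-controlled, dose-ranging trial in chronic spontaneous urticaria
(CSU): patient-diary endpoint scoring (daily UAS, UAS7 and its itch and
hive components, responder rules, time to the minimally important
difference), the two bespoke biomarker assays (basophil histamine
release assay normalization, IgG-anti-FcεRI competition ELISA), the
longitudinal efficacy analysis (MMRM with unstructured covariance,
LOCF/BOCF sensitivity ANCOVA, BHRA subgroup model, Spearman
correlation), Kaplan–Meier estimation, and the design layer (power,
stratified permuted-block randomization, Bayesian posterior-predictive
go/no-go). Patient-level data from such trials are access-controlled,
so the package ships a synthetic-cohort generator whose statistical
structure matches what the analyses assume; every downstream stage is
exercised and tested against it.

# The synthetic cohort

## Diary trajectories

Each patient carries a latent weekly-scale baseline severity
$b_i \sim N(\mu_0, \sigma_b^2)$ and a patient-level response log-rate
$g_i$. The desired daily-UAS mean on treatment day $d$ is

$$\mu_i(d) = \min\!\Big(\tfrac{b_i}{7}\, e^{g_i f(d)},\ c\Big),
\qquad f(d) = 1 - e^{-d/\tau},$$

an exponential-onset multiplicative effect ($\tau$ = `onset_days`,
default 10 days, chosen so the effect is near-maximal by week 4,
matching the rapid onset such trials report). The cap $c$ is the point
at which the larger ordinal component saturates (about 5.5 daily-UAS
points at the default itch/hive split).

Treatment effects are *proportional to baseline severity*: within each
arm-by-class group, $g_i \sim N(m, s^2)$ with $s$ =
`response_heterogeneity` (default 0.9) and the location $m$ calibrated
numerically (quadrature over the baseline distribution and $g$, plus
root finding) so that the group-mean week-8 change from baseline equals
the configured arm effect exactly, ceiling effects included. The
multiplicative form keeps severities positive — no floor bias at a
UAS7 of 0 — while the lognormal spread of $e^{g_i}$ reproduces the
clinically realistic mix of strong responders, complete remitters
(including under placebo) and nonresponders. Setting
`response_heterogeneity = 0` makes every patient respond with the group
mean effect, which is the configuration used by degenerate-case tests.

The latent autoimmunity-class shift is parameterized as the
class-versus-nonclass difference in mean week-8 change, centred within
the arm (class patients receive $(1-p)\cdot s_a$, non-class $-p\cdot
s_a$), so it moves the subgroup contrast without moving the arm mean.

Ordinal 0–3 session scores arise by thresholding a latent normal at
0.5/1.5/2.5. The latent location is set by numerically inverting the
threshold-mean map $h(m,\sigma) = \sum_{k=1}^{3}\Phi((m-k+0.5)/\sigma)$,
so configured means hold in expectation despite the ordinal censoring.
The latent noise is a shared day-level AR(1) process (stationary s.d.
`day_noise_sd`, coefficient `ar1_rho`) plus independent
session-by-component noise (`session_noise_sd`). Published summaries do
not identify the within-patient diary autocorrelation, so `ar1_rho` is
a free parameter (default 0.6, a moderate day-to-day persistence). The
between-patient s.d. of $b_i$ is sized by an approximate variance
decomposition (subtracting the within-patient weekly-sum noise variance
from the configured baseline variance) so the realized baseline UAS7
s.d. tracks the configured 7.3.

Dropout is a single discontinuation day per patient, uniform over the
56-day treatment period with probability `dropout_rate` (no published
hazard shape to match); diary sessions after it are missing, and
post-baseline sessions are additionally missing completely at random at
`session_missing_rate`. Baseline-week sessions are never removed,
mirroring the eDiary-completion eligibility requirement.

Reproducibility: one master seed; per-patient substreams are derived
deterministically from it, so enlarging a cohort never perturbs
existing patients, and identical (config, seed) pairs give byte-identical
serialized cohorts.

## What the generator emulates — and what it does not

The defaults mirror the published design magnitudes: four arms of
23/23/24/23 patients, baseline UAS7 27.5 (s.d. 7.3), week-8 mean UAS7
changes from −11.2 (placebo) to −20.7 (highest dose), ~41%
BHRA-positive prevalence tied to a latent type IIb autoimmunity class
with low total IgE, ~14% early discontinuation and sporadic missing
diary sessions. It does *not* emulate: pharmacokinetic exposure,
adverse events, item-level UCT responses, angioedema episodes, seasonal
or site effects, or informative (outcome-dependent) dropout — dropout
is MCAR by construction, whereas the MMRM only requires MAR. Passing
tests therefore certify the analytic machinery on data satisfying the
models' assumptions; they do not certify robustness to violations real
trials may exhibit.

## Assay forward models

The ELISA forward model is the exact inverse of the quantification
chain: a four-parameter logistic (4PL) absorbance–concentration curve
(parameters in `elisa_forward_params()`), a constant 630 nm plate
background, a 7-point threefold dilution series spanning the printed
0.014–10 ng/ml calibration range (a strict 6-point threefold series
cannot reach both endpoints, so the generator uses 7 points; the fitter
accepts either), a 16-serum healthy panel per batch, and duplicate
control-protein-spiked versus antigen-spiked wells per patient serum
whose concentration difference encodes the true relative reactivity.
BHRA raw data encode the true percentage release against a 5-serum
healthy panel. With noise set to zero, quantification recovers the true
biomarker values to numerical precision — a property the test suite
asserts — and positive noise settings leave recovery unbiased.

True biomarker levels are linked to the latent class by class-conditional
lognormal distributions (BHRA release centred at 2× the healthy
threshold in class patients versus 0.4× outside; IgG-anti-FcεRI
reactivity above versus below the UNR; total IgE centred at 28 versus
110 IU/ml, reproducing the low-IgE association). The class probability
is derived from the configured marginal BHRA+ prevalence and these
conditional positivity rates, so the marginal prevalence matches the
configuration in large samples.

# Endpoint derivation choices

The published endpoint definitions leave several details open; the
package fixes them as follows and tests them as stated:

* **Missing sessions.** A day with exactly one observed AM/PM session
  uses that session's itch+hive sum as the daily UAS (preserves data;
  the averaging rule applies only when both sessions are present).
* **Weekly completeness and proration.** A week is valid with ≥ 4
  observed days; component sums are prorated by $7/\text{days}$ and
  rounded half-up to one decimal. UAS7 is *defined* as itch7 + hive7
  after component proration, so the decomposition holds exactly for
  every patient-week.
* **Windows.** Week $w$ covers study days $7(w-1)+1 \ldots 7w$
  (calendar weeks anchored at the first dose; the last treatment week
  ends on day 56, the last dose day). Week 0, the baseline, is the 7
  days immediately before day 1 — the same window whose diary
  completion is an eligibility requirement.
* **Nonresponder rule.** A patient whose discontinuation day precedes
  day $7w$ is a nonresponder at week $w$ for all responder endpoints,
  regardless of any observed scores.
* **Itch MID.** The published MID for the weekly itch score is not
  stated; it is a configurable threshold (default 5 points).
* **Time to MID censoring.** Patients never reaching the MID are
  censored at their last valid on-treatment week (through week 8; the
  follow-up period does not extend the risk window).

# The longitudinal model

The MMRM is the multivariate-normal model of weekly change from
baseline with arm-by-visit cell means, country as a fixed covariate
(fixed levels, not pooled regions), and an unstructured within-patient
covariance across visits, estimated by REML. Baseline is *not* a
covariate — the model covariates are exactly country, treatment, visit
and visit-by-treatment. Missing visits contribute through the
likelihood (no imputation), which is valid under missing-at-random
dropout; the test suite includes a scenario where dropout depends on
the past observed outcome and checks that the MMRM week-8 contrast is
less biased than complete-case ANCOVA. All post-baseline weekly visits
enter by default (`visits = 1:8`), configurable to a sparser schedule.

The fit is delegated to `nlme::gls` (`corSymm` correlation with
per-visit variance weights); if the unstructured fit fails to converge
the model is refitted with compound symmetry and the covariance
structure is recorded on the object. Estimated covariance matrices are
symmetric positive semi-definite on every converged fit.

**Degrees of freedom.** Kenward–Roger denominator df are not available
for this engine. Contrasts use the approximate Satterthwaite method
(`emmeans`), which is accurate and affordable for covariances up to
five visits; beyond that the numerical approximation is unstable and
slow, and the package uses *containment* df — subjects minus
between-subject parameters, which equals the OLS residual df in the
single-visit case and is slightly conservative otherwise. The df method
is recorded in every contrast row. At these sample sizes the difference
between KR, Satterthwaite and containment t quantiles is below 2% of
the CI width.

**Sensitivity analyses.** LOCF replaces a missing week-8 change with the
last available post-baseline change; BOCF with the best — interpreted
as the most negative (most favorable for UAS7) — change. The imputed
value enters an ANCOVA on arm + country. With no missing data both
reduce exactly to the complete-case linear model.

**Subgroup model.** The BHRA subgroup analysis extends the primary
model with the BHRA subset indicator and the
visit-by-arm-by-BHRA interaction, reporting within-stratum
arm-versus-placebo contrasts. Collapsing the indicator to one level
recovers the primary model's estimates. No multiplicity adjustment is
applied anywhere; all CIs are unadjusted 95% intervals.

# Kaplan–Meier conventions

`km_fit` wraps the product-limit estimator (ties: events before
censorings at the same time). The median is the smallest time with
survival ≤ 0.5; when the curve sits exactly at 0.5 over a plateau the
midpoint of the plateau endpoints is reported — the convention that
produces half-week medians from weekly event grids. Without censoring
this equals the sample median.

# Design-layer conventions

* Power uses the evaluable n, `floor(n_per_arm * (1 - dropout))`, with
  a normal-approximation default and an exact t option; both satisfy
  the ≥ 90% planning check at the design inputs (difference 11, s.d.
  13, two-sided α 0.10, 30/arm, 10% dropout).
* The go/no-go rule codes benefit as positive-is-better magnitudes
  (UAS7 improvements are negated on entry). With a flat prior and known
  s.d., the posterior for the true effect is
  $N(\hat\delta, \sigma^2 \cdot 2/n_\text{interim})$ and the future
  estimate adds $\sigma^2 \cdot 2/n_{\text{phase3}}$; the reported
  probability is the upper tail at the threshold $\Delta^*$, with
  decisions at > 0.60 (go) and < 0.25 (no-go). Whether the threshold
  applies to the future *observed estimate* or the *true effect* is
  ambiguous in the published description; the predictive
  (observed-estimate) reading is the default and the posterior
  (true-effect) reading is available via `rule = "posterior"`. The
  threshold and phase 3 n have no published values and are therefore
  required arguments; the known s.d. defaults to the design s.d. 13.
* Randomization uses stratified permuted blocks (default block size 4,
  one per arm per block at 1:1:1:1; the published description does not
  state the block size). Complete blocks are exactly balanced.

# Numerical choices and degenerate inputs

* 4PL fitting is Levenberg–Marquardt on duplicate-averaged standards
  with data-driven starts; flat or non-monotone standards raise an
  error naming the plate. Inverse prediction is the analytic 4PL
  inverse; absorbances beyond the asymptotes and concentrations beyond
  the calibration range clamp to the range endpoints with a warning.
  Duplicates are averaged *after* inversion.
* Sample standard deviations (n−1) are used for both the BHRA
  2-s.d. threshold and the ELISA 3-s.d. UNR; positivity is inclusive
  for BHRA (≥ 10) and strict for the ELISA (> UNR), exactly as both
  rules are worded. The UNR is recomputed per assay batch, never
  pooled; the percent-change computation floors both visits at the
  follow-up batch's UNR.
* Report percentages round half-up to integers (so 13/23 prints as
  "13 (57)"); means and CIs round to one decimal.
* Zero-patient configs, single-country datasets, single-level subgroup
  indicators, empty time-to-event inputs and sub-threshold healthy
  panels all produce the documented errors, warnings or fallbacks
  rather than silent misbehaviour.

# Problem sizes used in the test and acceptance suites

Monte Carlo checks run at sizes chosen to make their tolerances sharp
but the suites quick: generator calibration at 2,000–2,500 patients
(3 Monte Carlo s.e. tolerances), dropout rates at 10,000 profile draws,
MMRM type-I error at 1,000 null replicates of 40 patients/arm over
three visits, contrast recovery at 250 patients/arm, and power
validation at 100,000 simulated trials. These sizes are the package's
own reporting choices and are stated here so results are reproducible
at exactly these scales.

# Known limitations

* The generator's trajectory model is invented structure around
  published endpoint-scale summaries; real diaries exhibit features it
  lacks (weekend effects, rescue-medication feedback on scores,
  informative dropout).
* The MMRM engine records Satterthwaite or containment df, not
  Kenward–Roger; inference at these n is practically identical, but
  exact KR reproduction is out of reach of this stack.
* Safety endpoints, adverse-event coding, PK/PD dose selection and
  quality-of-life instruments are out of scope.
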