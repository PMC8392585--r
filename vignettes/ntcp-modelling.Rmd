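---
title: "Modelling acute salivary dysfunction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acute salivary dysfunction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntcpxero)
```

This vignette is the package's account of the science it implements: the
dose-response model and its assumptions, the knobs that matter, what the
synthetic cohort generator does and does not emulate, and the numerical
decisions taken where the methodology left room.

## The problem and the model

Acute salivary dysfunction (dry mouth, CTCAE grade ≥ 2) develops in most
nasopharyngeal-cancer patients during radiotherapy because both parotid
glands and the minor salivary glands of the oral cavity sit in or near the
treated volume. The package models the probability of experiencing at
least one weekly grade ≥ 2 score during the treatment course as a
multivariable logistic function of reduced dose metrics and clinical
covariates:

$$p = \frac{1}{1 + e^{-(\beta_0 + \sum_i \beta_i x_i)}}$$

The dosimetric inputs are reductions of each organ's dose-volume
histogram (DVH):

* **Combined parotid glands (cPG).** Left and right glands are pooled
  into one organ (volumes summed on the union dose grid) because in
  nasopharyngeal treatments both glands receive substantial dose and an
  ipsilateral/contralateral split is not meaningful. The model uses the
  near-minimum dose **D98%** — the highest dose received by at least 98%
  of the combined volume — suggesting a whole-gland response once even the
  coldest regions receive moderate dose.
* **Oral cavity (OC).** A surrogate for the minor salivary glands. The
  model uses the generalized equivalent uniform dose at a strongly serial
  volume-effect parameter,
  $EUD = \left(\sum_i v_i D_i^{1/n}\right)^n$ with $n = 0.05$: high doses
  to even small sub-volumes dominate.
* **Clinical modifiers.** Age (continuous, per 5-year increase — salivary
  reserve declines with age) and smoking history (reduces serous salivary
  flow).

The built-in `reference_model()` carries the coefficients, standard
errors and organ reductions of this 4-variable model from a development
cohort of 132 patients with 90 events; it doubles as the
outcome-generating truth of the synthetic cohort generator, which closes
the loop for testing: simulate → develop → validate must recover what was
put in.

## DVH conventions and numerics

* **Bins.** Differential DVHs use half-open bins $(\ell, u]$ with the
  arithmetic bin centre as the representative dose for means and EUD.
  Cumulative and differential forms are exact inverses
  (`to_differential()` / `to_cumulative()`, round-trip ≤ 1e-9 cc).
* **Combining organs.** `combine_organs()` re-bins both DVHs onto the
  *union* of their dose grids with mass-preserving overlap allocation
  before summing. Because every source bin is exactly partitioned by the
  union edges, total volume and integral dose are conserved to rounding.
* **Point metrics.** D98% (and any Dx%) comes from linear interpolation
  on the cumulative curve rather than bin snapping, honouring the
  "near-minimum dose" intent without quantizing by bin width.
  `dose_at_volume()` returns the largest dose received by at least the
  requested volume fraction, so plateaus resolve to their upper edge.
* **EUD stability.** At $n = 0.05$ the exponent $1/n = 20$ overflows
  naive summation for doses in the tens of Gy. The implementation factors
  out the maximum bin dose,
  $EUD = D_{max}\left(\sum_i v_i (D_i/D_{max})^{1/n}\right)^n$, and treats
  zero-dose bins as exact zeros. Identities used as tests: $EUD(1)$ is
  the mean dose, a uniform dose is a fixed point for every $n$, and the
  grid is non-increasing in $n$.

## Metric screening

For each organ the 20 EUD values ($n = 0.05 \dots 1$) are screened
against the endpoint with a two-sample *t*-test (pooled-variance Student
form by default; Welch available) and the minimum-p metric wins. Ties are
broken toward larger $n$ — the weaker serial assumption. A screen with
fewer than two patients in a group or zero variance "does not converge";
if no EUD screen converges the cut-point family (D98%, D2%, Dmean, Dmax,
V30Gy–V70Gy in 5 Gy steps) is screened instead. Both families are always
tabulated so the analyst can see what the rule would have chosen, and a
winning metric whose p-value exceeds 0.05 is flagged rather than hidden.

## Endpoint derivation

Weekly grades are indexed from the first recorded assessment; the first
entry is the pre-treatment baseline and must be 0 (symptomatic patients
are excluded from this endpoint by design). The binary endpoint is any
grade ≥ 2 at any assessment; the first-event week is its index. The mean
grade is taken over **all** recorded assessments (baseline included, as
in the worked definition of the longitudinal endpoint), and the
longitudinal endpoint is mean grade ≥ 1.5. Actuarial incidence at week
*w* is the fraction of patients with a first event at or before *w* among
those still under observation; with no early treatment exits it reduces
to the crude cumulative proportion.

## Selection, fitting, and the sparse-cell guard

Candidate features (≈ 20 encoded clinical variables plus the two dose
metrics) enter an L1-penalized logistic model; the penalty minimizes
5-fold cross-validated binomial deviance (`rule = "1se"` gives the
sparser choice), with the fold assignment fixed by seed. The final model
is an **unpenalized maximum-likelihood refit** of the selected variables
— shrunken coefficients would not admit the Wald standard errors and odds
ratios that are reported. Dosimetric terms can be forced into the model
(`force_in`), since penalizing the variables the study exists to estimate
is a choice, not a necessity.

Two practical guards matter at realistic cohort sizes:

* **Sparse cells.** A binary covariate with (say) 3% prevalence in 200
  patients at a 70% event rate frequently has an empty or near-empty
  outcome-by-level cell; the logistic refit then quasi-separates and its
  coefficient diverges. Binary candidates therefore require at least
  `min_cell = 5` patients in every cell of their outcome cross-table;
  rarer flags are excluded from the candidate set (the same reasoning
  that keeps sparse medication variables out of such models in practice).
* **Separation.** Any remaining runaway coefficient (|β| > 15 on the
  logit scale) aborts the fit with the culprit named, rather than
  returning a numerically meaningless model.

## Internal validation

`bootstrap_optimism()` implements Harrell's procedure: refit the *whole*
recipe (selection included, by default) on each bootstrap resample,
evaluate it on the resample (apparent) and on the original cohort (test),
and subtract the mean difference from the original apparent performance.
Corrected AUC, calibration slope and calibration-in-the-large are
reported. Resamples with a single outcome class or a failed refit are
skipped; more than 10% skips aborts. The default is `B = 1000` resamples;
worked examples and the test suite use `B = 200`, which is ample to see
the correction while keeping runs fast.

Two honest caveats, both visible in the package's own outputs: with few
events per variable the optimism bootstrap is known to under-correct
discrimination (a heavily overfit null fit does not come all the way back
to AUC 0.5 — `scripts/acceptance.R` reports this quantity), and with the
selection step inside the loop the corrected estimate is noticeably
noisier than with a fit-only recipe.

## Calibration, goodness of fit, classification

* **Calibration slope** — slope of the logistic regression of outcomes on
  the logit of predicted probability (1 is ideal, < 1 indicates
  predictions too extreme).
* **Calibration-in-the-large** — intercept of the same regression with
  the logit prediction entered as a fixed offset (0 is ideal; positive
  means observed risk exceeds predicted). The definition of this quantity
  varies across the literature, so the probability-scale difference
  `mean(observed) − mean(predicted)` is reported alongside.
* **Hosmer–Lemeshow** — patients ranked by predicted risk and split into
  six equal-count groups (remainders to the lowest-risk groups; tied
  predictions never straddle a boundary); $\chi^2 = \sum (O-E)^2/E$ over
  both outcome cells, referred to $\chi^2_{g-2}$. That reference applies
  to probabilities fitted on the same data; for frozen external
  predictions it is reported with the same convention for comparability.
* **Classification** — positive call at predicted probability ≥ 0.65 by
  default; PPV/NPV with empty-denominator values reported as undefined
  (`NA`), never 0.
* **Residual flags** — patients with observed − predicted ≥ 0.7 are
  candidate radiosensitive outliers; ≤ −0.7 candidate radioresistant.

External validation (`external_validate()`) computes all of the above
from a frozen model object or JSON file and never refits the
coefficients; optionally the cohort's own refitted odds ratios are
attached for effect-size comparison.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: covariate
prevalences per cohort preset (development / NPC validation / mixed
head-and-neck validation), dosimetric moments for the combined parotids
(volume 53.3 ± 19.3 cc, mean dose 47.2 ± 9.5 Gy, max 74.2 ± 3.5 Gy, D98%
26.8 ± 9.5 Gy, D98–mean correlation 0.88) and the oral cavity (64.8 ±
20.4 cc, 46.7 ± 6.4 Gy, 71.9 ± 3.7 Gy), the reference model as
outcome-generating truth, and a conditional first-event-week profile
whose cumulative incidence lands on the 12 / 26.5 / 42 / 53 / 60 / 68.2 %
weekly pattern when the event rate is 68.2%.

Rather than drawing curve parameters and hoping the moments land, each
patient's (D98%, mean, max) triple is drawn from the target joint normal
(D98 and mean correlated at 0.88; draws violating the physical ordering
are redrawn or clamped — all rare-tail events) and a two-segment
piecewise-linear cumulative DVH is constructed that interpolates the
triple *exactly*: full volume to a knee $a$, falling to level $q$ at a
knot $c$, then to zero at the maximum dose. For a given $q$,

$$D98 = a + \tfrac{0.02\,(c-a)}{1-q}, \qquad
\bar D = \tfrac{a(1-q)}{2} + \tfrac{c}{2} + \tfrac{q\,D_{max}}{2},$$

is a linear system for $(a, c)$; $q$ is chosen from a grid (0.05–0.95) so
that plans with mean dose anywhere between the near-minimum and maximum
admit a valid geometry (high-mean plans need a heavy high-dose tail).
Because knots are included among the bin edges and density is constant
within segments, the binned mean, interpolated D98% and maximum are exact
by construction, and sample moments converge to the template targets.

Assumptions and non-goals worth knowing:

* The oral cavity has no tabulated D98%, so its low-dose knee is an
  assumed distribution (mean 24 Gy, SD 8 Gy, same correlation); the
  resulting EUD(n = 0.05) centres near 63 Gy, within the 45–65 Gy band
  used for the dose-response figures.
* Clinical covariates are drawn independently — no correlation structure
  between, e.g., age and comorbidities is emulated, because none is
  reported. Passing tests therefore demonstrate pipeline correctness, not
  robustness to real-world covariate collinearity.
* Age and BMI are truncated normals matched to medians and ranges (only
  medians/ranges are published); T-category and nodal prevalences are
  assumptions documented in `cohort_spec()`.
* Weekly grade trajectories are assembled to reproduce the drawn endpoint
  exactly (grade ≥ 2 from the first event week on, grade 0–1 background
  before); they emulate incidence timing, not grade kinetics.
* Only DVH-level realism is attempted — no 3D dose or anatomy.

`generate_validation_shift()` multiplies every patient's event odds by a
constant before the outcome draw, emulating the systematic incidence
increase seen between historical development data and later prospective
cohorts; frozen-model validation on such a cohort recovers
calibration-in-the-large ≈ log(multiplier) with slope ≈ 1 and unchanged
AUC — a pure recalibration failure, cleanly separated from a
discrimination failure.

## Nomogram

`build_nomogram()` maps each term to points
$100\,\beta_i (x - x_{i,\min}) / \max_j[\beta_j(x_{j,\max}-x_{j,\min})]$,
so the widest coefficient-times-range axis spans exactly 0–100 and the
reference value of each axis is its range minimum. Total points convert
back to probability through the linear predictor; reading integer points
off the printed scale stays within half a point per axis of the exact
calculation. Point allocations are invariant to rescaling all
coefficients by a common factor.

## Reproducibility and problem sizes

Every stochastic step (fold assignment, bootstrap, cohort generation)
takes an explicit seed, restores the caller's RNG state, and regenerates
bit-identically. Frozen models serialize to JSON with provenance
(package version, seed). The test suite exercises: dosimetric moment
convergence at 2000 draws, coefficient recovery at n = 5000, calibration
self-consistency at n = 10000, optimism correction at B = 200, and an
end-to-end simulate → develop → validate run at n = 200 — sizes chosen so
the whole suite runs in a couple of minutes while leaving Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

* The published cohort-level performance values (apparent/corrected AUC,
  HL statistic, validation slopes) depend on the unavailable patient
  data; nothing here claims to reproduce them, and the synthetic cohorts
  are a structural, not statistical, replica.
* The optimism bootstrap under-corrects discrimination in heavily
  overfit regimes (≈ 5 events per variable), as its own null-data output
  shows; interpret corrected AUC accordingly at small n.
* The t-test screen assumes approximately normal within-group metric
  distributions; with 20 correlated EUD screens per organ, the winning
  p-value is itself selection-biased and is used for ranking, not
  inference.
* The D98%/minimum-dose ambiguity for the parotids is resolved in favour
  of D98% (fraction 0.98) as the canonical reduction; fraction 1.0
  remains available through `dose_at_volume()`.
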