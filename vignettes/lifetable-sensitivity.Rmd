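---
title: "Life-table sensitivity analysis of social gradients in cancer net survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-table sensitivity analysis of social gradients in cancer net survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Net survival — the survival cancer patients would experience if their cancer
were the only cause of death — is routinely estimated in the
*relative-survival* (excess-mortality) setting: a patient's observed hazard
is decomposed as

$$\lambda(t, \mathrm{age}, \mathrm{EDI}, z) \;=\;
  \lambda_E(t, \mathrm{age}, \mathrm{EDI}) \;+\;
  \lambda_P(\mathrm{age}+t,\ \mathrm{year}+t,\ z),$$

where $\lambda_E$ is the excess (cancer-related) hazard and $\lambda_P$ the
expected (background) hazard of a demographically matched member of the
general population, read from national life tables.  The EDI (European
Deprivation Index) is an ecological deprivation score of the patient's
residence area; higher scores mean more deprivation, and Q1/Q5 denote the
least/most deprived national quintiles.

National life tables are typically stratified by sex, age, calendar year and
region but **not** by deprivation, while background mortality itself carries
a strong social gradient.  When an unstratified table is used, the
deprivation gradient of background mortality leaks into the estimated excess
hazard: the social gradient in net survival is mechanically overestimated.
This package implements the machinery to quantify that distortion by
sensitivity analysis: deprivation-specific life tables are *simulated* by
transferring the mortality gradient of an external source onto the original
table, and both the non-parametric and the flexible-model analysis are
repeated under each table.

## Deprivation-specific life-table simulation

The transfer is a per-stratum rate-ratio multiplication.  From an external
source providing smoothed mortality rates by sex, age (optionally year) and
five ordered deprivation levels, plus an overall rate,

1. sources on a 20-level scale (e.g. income vingtiles) are first collapsed
   to fifths by averaging levels 1–4, 5–8, 9–12, 13–16 and 17–20
   (`aggregate_vingtiles()`);
2. `compute_rate_ratios()` forms $rr(s, a, [y], d) = \text{rate}_d /
   \text{rate}_{\text{overall}}$; when no overall rate is published it is
   derived as the level-weight-weighted mean of the level rates (both
   conventions are supported because published sources differ);
3. `extend_years()` completes the calendar coverage by carrying the last
   covered year forward (and the first backward), matching the practice of
   duplicating the final published year over later follow-up years;
4. `apply_rate_ratios()` multiplies every (sex, age, year, region) cell of
   the base table by the five ratios, yielding a table stratified by
   quintile.

Two identities pin the construction down and are tested exactly: unit
ratios reproduce the base table cell-for-cell, and if the ratios have
level-weighted mean 1 the weighted mixture of the stratified rates equals
the base rate.  No renormalization is applied by default: the package
implements the literal per-stratum multiplication, and any
population-average preservation is the user's choice via the weights of the
source.  Rates are treated as hazards per person-year, constant on unit
age × year cells; death probabilities $q_x$ are converted on read via
$\lambda = -\log(1-q)$ when requested, since published tables are not
explicit about their encoding.

## Non-parametric arm: Pohar–Perme net survival

`pohar_perme()` implements the inverse-expected-survival-weighted estimator
of the cumulative excess hazard,

$$\hat\Lambda_E(t) = \sum_{u \le t}
  \frac{\sum_i dN_i(u)/S_{Pi}(u)}{\sum_i Y_i(u)/S_{Pi}(u)}
  - \int_0^t \frac{\sum_i Y_i(u)\,\lambda_{Pi}(u)/S_{Pi}(u)}
                   {\sum_i Y_i(u)/S_{Pi}(u)}\,du,
  \qquad \widehat{NS}(t) = e^{-\hat\Lambda_E(t)},$$

with variance $\sum_{u\le t}(\sum_i dN_i/S_{Pi}^2)/(\sum_i Y_i/S_{Pi})^2$.
Each subject's $S_{Pi}(u) = \exp(-\Lambda_{Pi}(u))$ integrates the life-table
hazard *exactly* along the diagonal (age at diagnosis $+u$, year of
diagnosis $+u$), splitting at every integer age and calendar-year crossing.
Numerical choices:

* the population integral uses the trapezoid rule on a grid that refines
  every interval between consecutive observed times to steps of at most
  1/52 year — well below the estimator's sampling noise;
* ties between deaths and censorings are handled by the usual risk-set
  convention $Y_i(u) = 1\{T_i \ge u\}$ (deaths first);
* ages above the oldest tabulated age and years outside the table are
  clamped to the nearest covered cell, since registry follow-up routinely
  outlives the tables;
* the estimator is unconstrained ($\widehat{NS}$ may exceed 1), and curves
  are truncated with a warning once the risk set empties.

`age_standardized_ns()` combines group-specific estimates with
International Cancer Survival Standard-style weights over age groups
[15,45), [45,55), [55,65), [65,75), 75+ (weights 0.07, 0.12, 0.23, 0.29,
0.29).  No authoritative weight set is implied — the weights are fully
configurable and none of the package's statistical checks depend on them.
Empty groups are dropped with renormalized weights and a warning.
`deprivation_gap()` reports $100\,(\widehat{ASNS}_{Q1}(h) -
\widehat{ASNS}_{Q5}(h))$ in percentage points with the delta-method
standard error and a symmetric 95% CI, matching the convention in which
such gaps are published; log(−log) intervals for single curves are
available by flag.

## Flexible arm: penalized-spline excess hazard

`fit_excess_hazard()` maximizes the penalized likelihood

$$\ell_{pen}(\beta) = \sum_i \big[\delta_i \log(\lambda_E(T_i; x_i) +
  \lambda_{Pi}(T_i)) - \Lambda_E(T_i; x_i)\big]
  - \tfrac12 \sum_m s_m\, \beta' P_m \beta,$$

with $\log \lambda_E$ built from cubic B-spline bases.  Four candidate
forms express the deprivation effect:

1. tensor(time, age) — no EDI effect;
2. adds a smooth (or linear) EDI main effect — proportional;
3. adds a tensor(time, EDI) interaction — time-dependent;
4. replaces everything by the full three-way tensor(time, age, EDI).

The EDI margins of forms 2–3 are constrained to exclude the constant
function (the B-spline partition of unity makes the constant direction the
all-ones coefficient vector), so the blocks are identifiable against the
baseline tensor and the nesting $1 \subset 2 \subset 3 \subset 4$ holds
when the marginal bases are shared.  Per-margin second-order difference
penalties (Frobenius-normalized) act on each tensor block.

Default bases are deliberately modest, matched to the smoothness of
registry-scale hazards: time with interior knots at 0.5 and 2 years on
[0, 6] (follow-up is truncated at 6 years for modelling, so the upper
boundary knot sits at 6); age and EDI with one interior quantile knot; the
three-way tensor of form 4 with knot-free cubic margins (4 × 4 × 4
coefficients), since an 85-dimensional interaction surface is neither
estimable nor needed at these sample sizes.  All of this is configurable
through `excess_basis_config()`.

* **Quadrature.** $\Lambda_E(T_i)$ uses Gauss–Legendre nodes *per
  inter-knot piece* of the time basis (default 6 per piece).  The integrand
  is analytic within a piece, so doubling the node count changes the fitted
  log-likelihood by well under $10^{-6}$ relative — a tested invariant.  A
  single panel across knots would converge only algebraically because the
  spline is merely $C^2$ there.
* **Optimization.** Damped Newton with analytic score and Hessian
  (the observed-data term $\log(e^\eta + \lambda_P)$ is convex in $\eta$,
  the cumulative-hazard term concave; the penalized Hessian is regularized
  by an escalating ridge if a Cholesky step fails), line search by halving,
  up to 5 deterministically jittered restarts.
* **Smoothing selection.** The corrected AIC
  $-2\hat\ell + 2\,\mathrm{EDF} + 2\,\mathrm{EDF}(\mathrm{EDF}+1) /
  (n_{events}-\mathrm{EDF}-1)$ (with $\hat\ell$ the *unpenalized*
  log-likelihood at the penalized optimum and $\mathrm{EDF} =
  \mathrm{tr}(H_{pen}^{-1} H_{unpen})$) is minimized coordinate-wise over
  $\log_{10} s \in [-2, 6]$, coarse grid first and local refinement to 0.5
  resolution, with warm-started Newton fits.  By default the margins of a
  tensor block share one multiplier; `tie_margins = FALSE` frees them.
  Marginal-likelihood (LAML) selection is out of scope.
* **Selection across forms.** `select_model()` fits all four forms and
  returns the minimum-AICc fit, breaking ties below $10^{-6}$ toward the
  lower form code (parsimony).  Forms 2–3 warm-start their baseline
  smoothing from form 1's selected value.
* **Inference.** The coefficient covariance is the inverse penalized
  observed information; EHR curves (`ehr_vs_edi()`,
  `ehr_p90_p10_over_time()`) use the delta method on the log scale, with
  the conventional reference points EDI $p10 = -3.9$ and $p90 = 4.4$.

## The synthetic registry world

Because real registry cohorts cannot be redistributed, `sim_config()` /
`gen_truth_tables()` / `gen_cohort()` generate a cohort with known ground
truth whose observed mortality is the sum of a deprivation-graded
background hazard and a configurable cancer excess hazard:

* diagnoses uniform over 2006–2009, administrative censoring at mid-2013
  (follow-up 3.5–7.5 years);
* age at diagnosis from a truncated normal (mean 65, sd 12) on [15, 99];
* EDI from a shifted lognormal calibrated to the published national
  summaries (median −0.75, range ≈ −17 to 51); only these summaries, not
  the true French distribution, are matched.  Quintile cut points are the
  theoretical 20/40/60/80 percentiles of that marginal, with lower-closed
  assignment;
* background mortality from a Gompertz hazard
  $a_0 e^{b\,\mathrm{age}}$ ($a_0 = 3.7\times 10^{-5}$, $b = 0.09$, a
  −1%/year calendar drift, male rates 1.25× female), multiplied by quintile
  rate ratios defaulting to (0.80, 0.90, 1.00, 1.15, 1.35) — a gradient of
  the order reported for European mortality by education/income, without
  claiming those exact ratios;
* excess hazard Weibull (shape 0.8, scale 8, i.e. a declining hazard with
  5-year baseline net survival ≈ 0.5) times a deprivation multiplier
  $\exp\{\beta(\mathrm{EDI} + 3.9)\}$ with $\beta = \log(\mathrm{EHR}_{p90/p10})/8.3$,
  optionally decaying exponentially in time (form 3);
* latent background times are drawn by exact inversion of each subject's
  piecewise-constant cumulative hazard along the life-table diagonal
  (`invert_piecewise_hazard()`); latent excess times by closed-form Weibull
  inversion (forms 1–2) or linear inversion of a fine-grid (1/104-year)
  cumulative hazard (form 3); the observed time is the minimum with the
  censoring time and the latent cause is recorded.

What the generator does *not* emulate: cancer-site- and stage-specific
hazard shapes, regional heterogeneity (one region by default), spatial
autocorrelation of EDI, or non-administrative loss to follow-up.  Passing
tests therefore demonstrate the estimators' correctness and the
life-table-distortion mechanism under a clean competing-hazards world, not
the magnitude of the distortion in any real registry.

## The three-analysis comparison

`run_comparison()` analyzes one cohort under the original unstratified
table ("main") and any number of simulated stratified tables, runs both
arms, and classifies each sensitivity analysis against the main one:
*inversed* (gap sign flips with disjoint CIs), *inconsistent* (the selected
form changes to or from "no effect"), *consistent* (same form, overlapping
CIs, no shrinkage), *attenuated* (same sign, smaller gap).  The published
classifications of such comparisons are narrative; these rules are a
declared operationalization with explicit precedence, not a claim of
equivalence.  `write_report()` emits a versioned JSON summary plus
delimited EHR curve files, deterministically ordered.

## Problem sizes and reproducibility

The test suite exercises: exactness of the estimator against independent
direct-summation oracles on 3–5-patient cohorts; reduction to
exp(−Nelson–Aalen) with a null life table (n = 200); cohort-level
Monte-Carlo checks at n = 30,000–50,000; a 50-replicate × n = 20,000 gap
study (null deprivation effect, background gradient Q5/Q1 = 1.5) for
unbiasedness under the correct table and inflation under the unstratified
one; 25-replicate recovery of EHR$_{p90/p10}$ = 1.3 at n = 20,000; and
selection operating characteristics at n = 5,000 (null truth) and
n = 2,500 (strong effect, EHR = 2.0, where detection power is already
essentially 1).  `scripts/acceptance.R` re-runs the same designs at
moderately reduced replicate counts and writes the headline numbers as
JSON; all randomness descends from its `--seed` argument.

## Known limitations

* The estimators assume the life table is correct for the cohort's
  background mortality; the package quantifies sensitivity to the
  deprivation stratification, not to other life-table misspecifications.
* The AICc definition uses EDF-based small-sample correction with the
  event count as the effective sample size; AICc values are comparable
  only within one implementation and data set, which is all that model
  selection requires.
* The concordance classifier mixes CI overlap and model-selection
  judgments; boundary cases are sensitive to its declared thresholds.
* Period/hybrid analyses, cure models, multiple imputation for missing
  deprivation scores, and covariates beyond (time, age, EDI) are out of
  scope.
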