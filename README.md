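# depnetsurv

Sensitivity of social gradients in cancer **net survival** to the
deprivation stratification of the background **life tables**.

## The problem

In the relative-survival (excess-mortality) framework, a cancer patient's
observed hazard is decomposed as

    λ(t, age, EDI, z) = λ_E(t, age, EDI) + λ_P(age + t, year + t, z)

where λ_E is the excess (cancer-related) hazard and λ_P the expected
hazard of a demographically matched member of the general population, read
from national life tables. National tables are stratified by sex, age,
year and region but usually **not** by deprivation, although background
mortality is strongly socially graded. Analyses based on such tables
mechanically push the social gradient of *background* mortality into the
estimated *excess* hazard, overstating the deprivation gap in net
survival — in extreme cases (e.g. cancers with very low excess mortality)
even reversing conclusions.

`depnetsurv` provides, for registry-style cohorts scored with an
ecological deprivation index (EDI, Q1 = least to Q5 = most deprived
national quintile):

* **Life tables** — reading/writing, validation, exact integration of the
  expected hazard along each patient's follow-up diagonal
  (`life_table()`, `cumulative_expected_hazard()`);
* **Deprivation-specific life-table simulation** — transfer of an external
  source's mortality gradient by per-stratum rate-ratio multiplication,
  including vingtile-to-quintile aggregation and calendar-year
  carry-forward (`aggregate_vingtiles()`, `compute_rate_ratios()`,
  `extend_years()`, `apply_rate_ratios()`);
* **Non-parametric arm** — the Pohar–Perme net-survival estimator with
  variance, age standardization and the Q1–Q5 deprivation gap with 95% CI
  (`pohar_perme()`, `age_standardized_ns()`, `deprivation_gap()`);
* **Flexible arm** — penalized-spline excess-hazard regression with four
  deprivation-effect forms (none / proportional / time-dependent /
  time- and/or age-dependent), corrected-AIC smoothing and form selection,
  and excess-hazard-ratio curves with delta-method CIs
  (`fit_excess_hazard()`, `select_model()`, `ehr_vs_edi()`,
  `ehr_p90_p10_over_time()`);
* **Synthetic registry world** — cohorts with known ground truth whose
  mortality is background (Gompertz × quintile gradient) plus a Weibull
  excess hazard with a configurable deprivation effect (`sim_config()`,
  `gen_truth_tables()`, `gen_cohort()`);
* **Orchestration** — the three-analysis comparison (main vs sensitivity
  tables) with concordance classification and a JSON/CSV report
  (`run_comparison()`, `write_report()`).

## Worked example

Simulate a registry cohort in which deprivation has **no** effect on the
cancer excess hazard but background mortality rises across quintiles, then
compare the analysis under the true stratified table with the analysis
under the unstratified one:

```r
library(depnetsurv)

cfg <- sim_config(n = 20000, edi_form = 1,
                  background_rr = c(0.8, 0.9, 1.0, 1.1, 1.2))
tt  <- gen_truth_tables(cfg)
gc  <- gen_cohort(cfg, tt$stratified, seed = 1000 + 5)

rep <- run_comparison(gc$cohort, tt$base,
                      list(strat = tt$stratified), do_model = FALSE)
print(rep)
```

```
Life-table sensitivity comparison (5-year gaps)
  main       gap =   5.46 pp (2.53; 8.38)
  strat      gap =   2.12 pp (-0.82; 5.07)  [attenuated]
```

The true 5-year deprivation gap is 0. The unstratified ("main") analysis
reports a positive gap of 5.5 percentage points; re-analyzing the *same*
cohort with the deprivation-stratified table shrinks it toward 0 (and over
replications its mean is 0). The gap printed for each analysis is
`100 * (ASNS_Q1(5) − ASNS_Q5(5))`, age-standardized net survival estimated
by the Pohar–Perme method, with a symmetric delta-method 95% CI.

The flexible arm on the same kind of data (here with a true proportional
effect, EHR_p90/p10 = 1.3):

```r
cfg2 <- sim_config(n = 20000, edi_form = 2, log_ehr_p90_p10 = log(1.3))
tt2  <- gen_truth_tables(cfg2)
gc2  <- gen_cohort(cfg2, tt2$stratified, seed = 11)
fit  <- fit_excess_hazard(gc2$cohort, tt2$stratified, form = 2)
ehr_p90_p10_over_time(fit, time_grid = 1, ages = 65)
```

```
  time age     ehr       lo       hi
1    1  65 1.29504 1.252723 1.338787
```

i.e. the excess hazard of a patient at the 90th EDI percentile (4.4) is
estimated at 1.30 times that of a patient at the 10th percentile (−3.9),
recovering the simulated effect.

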