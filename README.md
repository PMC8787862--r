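# rtmicrocost

Micro-costing and causal comparison of two rotational intensity-modulated
radiotherapy (IMRT) techniques — volumetric modulated arc therapy (VMAT)
and helical tomotherapy (HT) — for high-risk prostate cancer with pelvic
nodal irradiation. The package is aimed at health economists and
radiation-oncology teams who want to (i) value radiotherapy preparation
and delivery bottom-up from chronometer-style resource-use logs, and
(ii) compare costs and ordinal CTCAE toxicity between non-randomized
treatment groups with propensity-score weighting.

## What it computes

**Micro-costing.** Every staff minute is valued at the role's hourly full
wage, `annual full gross wage / workable yearly hours`. Every machine
minute is valued at an hourly equipment rate built from straight-line,
undiscounted replacement and running costs:

    rate = (price / lifespan + external maintenance + QC&IM) / annual operating hours

where the annual machine quality-control and internal-maintenance (QC&IM)
labor cost is

    QC&IM = Σ_labor  hourly full wage_labor × annual dedicated hours_labor

summed over the medical physicist and the biomedical technician.
Lifespans are 12 years for accelerators and 5 years for a treatment
planning system (TPS); HT carries no separate TPS line because its
accelerator price includes it. Per-patient costs decompose into nine
components (labor/equipment for image registration & contouring, inverse
planning, patient-specific QC, day-0 setup verification, and treatment
sessions) with `total = planning + session` as an exact accounting
identity.

**Stabilized IPTW.** The propensity score `e(x) = P(HT | x)` is estimated
by logistic regression on age, performance status, cT stage, cN stage and
capped PSA. Patients are weighted by the stabilized inverse probability
of the treatment received, `w = P(HT)/e(x)` for HT and
`w = P(VMAT)/(1 − e(x))` for VMAT, so the pseudo-population keeps the
sample size. Balance is assessed with standardized differences `d`
(continuous, binary, and the generalized Mahalanobis form for multilevel
covariates).

**Outcome models.** Weighted least squares for total cost (HT − VMAT
difference in euros, adjusted for sequential vs simultaneous-integrated-
boost plans) and weighted proportional-odds (cumulative logit) models for
the collapsed toxicity grades 0 < 1 < 2 < 3–4, both with robust sandwich
standard errors.

**Uncertainty.** Percentile bootstrap confidence intervals for group mean
costs (patients resampled within arm; rank-based trimming, e.g. 25 of
1,000 iterates per tail) and one-way ±20% sensitivity analysis producing
tornado-plot tables.

**Synthetic cohorts.** A seeded generator emulates the study structure:
106 VMAT / 49 HT patients, confounded assignment driven by the baseline
covariates, 34-fraction SIB vs 40-fraction sequential plans, log-normal
session times with the published learning curve (VMAT medians 20/15/13
minutes across session strata, HT 18/18/17) and a proportional-odds
toxicity model with acute effects favoring HT and null late effects.
Default unit costs are placeholders calibrated so the generated cohort
reproduces the published per-arm component cost means.

## Worked example

```r
library(rtmicrocost)

cohort <- generate_cohort(default_cohort_config(seed = 2026))
costs  <- cost_cohort(cohort$resource_use, default_unit_costs(), cohort$patients)
w      <- weight_cohort(cohort$patients)

balance_table(cohort$patients, w$stabilized_weight)
#>   covariate          kind       unweighted_d weighted_d
#> 1 age                continuous        0.360   0.0975
#> 2 performance_status binary            0.281  -0.0279
#> 3 c_t_stage          multilevel        0.345   0.198
#> 4 c_n_stage          binary            0.300  -0.0197
#> 5 psa                continuous        0.246   0.000569
```

Assignment is confounded (unweighted `d` up to 0.36); stabilized IPTW
shrinks the imbalance toward zero (at n = 155 some residual noise
remains, here on cT stage).

```r
ht <- costs$arm == "HT"
summarize_costs(costs[ht, ], w$stabilized_weight[ht])
#>    component                  mean     sd
#>  1 image_registration_labor   40.9  43.4
#>  ...
#>  9 session_accelerator      2373.  158.
#> 10 planning_cost             209.  103.
#> 11 session_cost             2929.  195.
#> 12 total_cost               3138.  230.

bootstrap_mean_cost(costs$total_cost, costs$arm, w$stabilized_weight,
                    bootstrap_config(seed = 2027))
#>   arm       n  mean ci_low ci_high
#> 1 VMAT    106 2550.  2499.   2602.
#> 2 HT       49 3138.  3075.   3204.

weighted_linear_model(costs$total_cost, cohort$patients$arm,
                      cohort$patients$plan, w$stabilized_weight)
#>   outcome    model  term   estimate    se statistic  p_value weighting
#> 1 total_cost linear arm_ht     591.  30.3      19.5 8.15e-85 IPTW
```

Delivery dominates HT costs (accelerator ≈ 2,373 € of a 3,138 € total in
this draw) and the adjusted HT − VMAT difference is about 590 €, the
direction and order of magnitude of the published 525 € gap. The whole
pipeline — simulate → cost → weight → analyze → bootstrap → tornado, with
CSV outputs and a digest manifest — runs as

```r
run_pipeline("out/", config = default_cohort_config(), seed = 42)
render_tables("out/")
```

or from a shell via `inst/scripts/rtmicrocost.R`.

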