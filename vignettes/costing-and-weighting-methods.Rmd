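---
title: "Micro-costing and weighted comparison of rotational IMRT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-costing and weighted comparison of rotational IMRT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rtmicrocost implements a complete cost-and-toxicity comparison of two
rotational IMRT delivery techniques, volumetric modulated arc therapy
(VMAT) and helical tomotherapy (HT), in high-risk prostate cancer with
pelvic nodal irradiation. Treatment assignment in this setting is not
randomized — centers typically own one machine — so the comparison
combines bottom-up (micro-) costing with stabilized
inverse-probability-of-treatment weighting (IPTW). This vignette is the
package's own account of the models, the tunable parameters, and the
choices made where the design was genuinely open.

## The costing model

The costing perspective is the hospital's; only resources that differ
between the two techniques are valued, from treatment planning through
the last delivery session. The analytic horizon is under three months,
so no discounting is applied. All default monetary parameters are
expressed in 2019 euros, taxes included.

**Labor.** Each staff minute is valued at the role's hourly full wage:
the average annual gross wage including payroll taxes divided by
workable yearly hours (default 1,600 h/year for all six roles:
radiation therapist, dosimetrist, medical physicist, radiation
oncologist, resident, biomedical technician). Simultaneous presence of
several roles is costed additively per role-minute, which matches
chronometer logs that record all personnel time.

**Equipment.** A machine hour costs

$$\text{rate} = \frac{\text{price}/\text{lifespan} +
\text{external maintenance} + \text{QC\&IM}}{\text{annual operating hours}},$$

straight-line and undiscounted, with 12-year accelerator and 5-year TPS
lifespans. The annual machine quality-control and internal-maintenance
(QC&IM) labor cost is the sum over the medical physicist and the
biomedical technician of hourly wage × annual dedicated hours. QC&IM
hours are stored per machine (defaults 194.5 h/year for the VMAT
accelerator, 144 h for HT) because the two techniques demand different
upkeep workloads.

Two allocation conventions deserve note. First, the QC&IM annual cost
is folded into the accelerator's numerator before dividing by operating
hours: QC&IM is machine upkeep, and this routes it to patients through
machine occupancy exactly like maintenance. An alternative — spreading
it per patient-year — would decouple it from machine time; the fold-in
is the package's documented convention. Second, the VMAT TPS is
amortized over its own annual operating-hours parameter (default equal
to the accelerator's 2,513 h); HT has no TPS line at all, because the
HT accelerator price includes its integrated planning system, so HT TPS
components are forced to zero by construction.

Internally all arithmetic is carried at full double precision; only
printing rounds to centimes. Per patient, nine components (labor and,
where applicable, machine occupancy for image registration &
contouring, inverse planning, patient-specific QC, day-0 setup
verification, and sessions) satisfy the exact identities
`planning + session = total`.

**Default unit costs are calibrated placeholders.** Catalog prices,
maintenance contracts and wage schedules of the source study are not
public. The defaults therefore sit at plausible French 2019 values
(e.g. accelerator prices 2.7 M€ VMAT / 3.6 M€ HT, physicist wage
90 k€/year) and the two least-documented parameters — the accelerators'
annual external maintenance — are back-solved so that, at the published
session-time medians and operating hours, the default synthetic cohort
reproduces the published per-arm session-accelerator cost means. Any
real costing exercise should replace the whole table via
`unit_cost_table()` or a YAML file.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is exercised.

**Covariates and assignment.** Baseline covariates are drawn from the
pooled study margins: age ~ Normal(68.6, 7.7) years; performance status
1–2 with probability 24/155; cT levels with probabilities
(23, 45, 82, 5)/155; cN1 with probability 21/155; PSA log-normal
(meanlog log 13, sdlog 0.7, giving mean ≈ 16 and SD ≈ 13 ng/ml) capped
at 100 ng/ml. The cap value is never stated by the study; 100 ng/ml is
a clinically conventional truncation for high-risk series and is the
package's choice. Assignment to HT follows a logistic model whose
default log-odds (cN1 +1.02, performance status +0.73, cT2 −0.81,
cT3 −0.27, cT4 +0.85, age +0.035/year, PSA +0.015/(ng/ml)) reproduce
the direction and rough size of the published arm imbalances, e.g. cN1
9.4% in VMAT vs 22.4% in HT.

The observed cohort has fixed arm sizes (106/49), so the default
generation mode draws assignment probabilities and then fills the HT
arm by weighted sampling without replacement. That conditional filling
is close to, but not exactly, the unconditional logistic law, so
`generate_patients(..., exact_sizes = FALSE)` provides plain Bernoulli
assignment; parameter-recovery checks use that mode, cohort emulation
uses the exact-size mode.

**Timing.** Session times are log-normal, parameterized by the median
so that the configured stratum medians are hit exactly: VMAT 20/15/13
minutes and HT 18/18/17 for session strata {1}, {2–3}, {4+}, encoding
the learning-curve effect seen for VMAT. The dispersion default
`sdlog = 0.2` is a modest service-time noise level; it inflates session
cost *means* about 2% above the medians-based calibration target, a
bias the package accepts knowingly (the published inputs are medians).
Setting `sdlog = 0` gives degenerate draws for exact arithmetic.
Session staffing is a per-arm factor (personnel minutes per machine
minute) back-solved from the published session labor means.

**Planning times.** The study publishes planning-phase costs, not
times, so the per-phase time means/SDs are back-solved at the default
unit costs from the published component means. Times are drawn from a
gamma distribution matched to that mean and SD rather than a
zero-truncated normal: several components have SD larger than the mean,
where truncation would shift the realized mean well above its
calibration target, while the gamma keeps the mean exact and the
support positive.

**Toxicity.** Grades 0 < 1 < 2 < 3–4 follow a proportional-odds model.
Cutpoints are calibrated from the HT grade margins per endpoint
(gastro-intestinal, genito-urinary, sexual) and window (acute ≤ 3
months; late 6–24 months), with zero cells smoothed to 1% before taking
logits so all three cutpoints stay finite. Treatment log-odds default
to +0.6 (GI, GU) and +0.3 (sexual) acutely — positive meaning worse
grades under VMAT — and 0 in the late window: acute effects favoring
HT, null late effects. Acute event months are uniform on (0, 3], late
on [6, 24]. Toxicity follow-up is observed with probability 98/106 in
the VMAT arm and 1 in HT; analyses drop unobserved patients.

**Determinism.** One RNG stream per cohort, seeded from the
configuration, with fixed substream order: patients, then resource use,
then toxicity (acute before late, endpoints in GI/GU/sexual order).
Identical configurations regenerate byte-identical CSVs.

**What the generator does not emulate.** No center-level clustering
(the source data could not model centers either), no dosimetry, no
Gleason scores, no correlation between planning times and session
times, and no cost consequences of acute toxicity. Passing tests on
synthetic cohorts therefore demonstrate correctness of the estimators
under the generator's law, not robustness to real-world features such
as clustered assignment or informative follow-up.

## Weighting and balance

The propensity model is a maximum-likelihood logistic regression of the
HT indicator on the five adjustment covariates; cT enters as indicator
contrasts against cT1, PSA enters capped and linear (whether the source
analysis logged it is unstated; capped-linear is the package's choice).
Stabilized weights multiply the inverse probability of the received
treatment by the marginal arm share, so weights sum to about n per arm.
Fitted probabilities at 0 or 1 raise an explicit error rather than
being truncated; an optional clip exists nowhere by default because the
observed study reported no trimming.

Standardized differences use the HT − VMAT sign convention (the
magnitude is what matters; the sign is fixed to make tests
deterministic). Weighted variants use frequency-weighted moments
(weights read as pseudo-population counts, variance denominator
Σw − 1), which reduces exactly to the unweighted formula at unit
weights. For covariates with more than two levels the generalized
Mahalanobis form over the L − 1 level-proportion contrasts is used,
with the average of the two within-arm multinomial covariance matrices.
The weighted-variance convention behind any published weighted-d column
is generally unstated, so exact reproduction of weighted d values is
not a goal; unweighted d values are reproduced to 3 decimals.

## Outcome models

Costs: weighted least squares of total cost on an HT indicator plus a
sequential-plan indicator; the arm coefficient is the adjusted HT −
VMAT euro difference. Toxicity: weighted proportional-odds regression
of the collapsed grade on a VMAT indicator plus the plan indicator,
parameterized so a positive coefficient means higher odds of a worse
grade under VMAT. With only two observed grade categories the
cumulative-logit model *is* binary logistic regression, and the
implementation reduces to it explicitly.

Both models report robust (sandwich) standard errors with the weights
treated as fixed — the weights are estimated, and the usual
model-based variance would be inconsistent under weighting. For the
proportional-odds fit the sandwich is assembled from analytic
per-observation cumulative-logit scores around the inverse observed
information. P-values are Wald; whether the source analysis used Wald
or likelihood-ratio tests is unstated, and Wald is the package's
documented convention. Treating estimated-weight uncertainty as fixed
is mildly conservative for the stabilized-IPTW arm effect.

## Uncertainty

**Bootstrap.** Patients are resampled with replacement within arm;
stabilized weights are re-used, not re-estimated, per resample (the
resampled quantity is the weighted mean cost; weight re-estimation is
available by re-running the weighting stage on each resample but is not
the default). The interval is rank-based percentile: with B iterates at
level 1 − α, the ⌈αB/2⌉ smallest and largest iterates are dropped and
the interval is the adjacent order statistics — with B = 1,000 and 95%,
drop 25 per tail, keep `[s(26), s(975)]` — no interpolation. The rank
computation rounds `αB/2` to 9 decimals before the ceiling so that
binary floating point cannot push 25.000…04 up to 26. Fewer than
2/(1 − level) iterations (40 for 95%) is an error, and the point
estimate is the full-sample weighted mean, independent of B.

**Tornado.** One parameter at a time is set to (1 ± δ) times baseline
(default δ = 0.20), the group mean total cost is recomputed, and rows
are sorted by descending range. The default parameter set: accelerator
price, external maintenance, annual operating time, accelerator
immobilization time, TPS price, and per-role wages and labor times.
"Accelerator immobilization time" scales session and day-0 setup
machine minutes jointly, both being machine-occupancy components; this
joint definition is what reproduces the published 12.1% (VMAT) and
15.5% (HT) total-cost decreases under a 20% cut. The published sentence
pairs those figures with both an operating-time increase and an
immobilization-time decrease; component arithmetic shows both figures
follow from the immobilization-time perturbation alone, so the package
attributes them to it and leaves the operating-time pairing as a noted
ambiguity. Wages and prices enter linearly (symmetric bars); operating
time enters hyperbolically (asymmetric bars: +25% cost at −20% hours,
−16.7% at +20%).

## Numerical and degenerate-input behavior

Probabilities outside [0, 1], non-monotone toxicity cutpoints,
non-positive lifespans or operating hours, unknown roles, machines,
phases or sensitivity parameters, empty arms, all-identical grades,
collinear designs and zero pooled variances raise explicit errors —
nothing is silently clamped or skipped. Accounting identities are exact
to 1e−9 euro. Cost summaries normalize weights to sum to n, making them
invariant to weight rescaling and reducing to ordinary means/SDs at
unit weights.

## Problem sizes used by the test suite

The suite exercises the study-sized cohort (106/49) end-to-end and uses
larger Bernoulli-mode cohorts (n = 20,000) for balancing and
parameter-recovery properties, 10,000 draws for median checks, and 500
replicates of a 1,000-iterate bootstrap (n = 60 per replicate) for
coverage, chosen to keep Monte-Carlo error well below the asserted
tolerances. The bootstrap coverage band asserted is 93–97% at a nominal
95%.

## Known limitations

* The default unit costs are calibrated placeholders, not a price
  survey; absolute euro levels are only as meaningful as the inputs.
* Estimated-weight and estimated-calibration uncertainty are not
  propagated into the bootstrap intervals.
* The generator's independence assumptions (planning vs session times,
  toxicity vs costs) are simplifications; between-center heterogeneity
  is absent.
* Costs of managing acute toxicity, androgen deprivation therapy,
  bunker construction, record-and-verify systems and patient-QA
  software are out of scope by design, mirroring the source study's
  exclusions.
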