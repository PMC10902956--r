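---
title: "Model and methods: a calibrated Markov cost-utility model for DRd vs KRd in relapsed-refractory multiple myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmmcea)
```

## The decision problem

Two triplet regimens for relapsed-refractory multiple myeloma are
compared from a payer perspective: daratumumab + lenalidomide +
dexamethasone (DRd, planned 25 treatment cycles) versus carfilzomib +
lenalidomide + dexamethasone (KRd, planned 18 cycles).  No head-to-head
trial exists; the relative effect enters as network-meta-analysis
hazard ratios — 0.60 (0.43–0.82) for progression and 0.46 (0.28–0.75)
for overall survival, DRd vs KRd.  The economic question is whether
DRd's extra drug cost is justified at a willingness-to-pay (WTP) of
$1,290 per QALY.

## Model structure and assumptions

The cohort model has three states — progression-free (PFS),
post-progression (PD), death — in monthly cycles over a 10-year
horizon (120 cycles, configurable).  Everyone starts in PFS; PD cannot
revert; death is absorbing.  Treatment is never discontinued early;
after the planned treatment period a progression-free patient receives
supportive care only.

**Exponential baselines.**  No baseline survival curves are published
for this comparison, only a life-year total per arm, so the minimal
assumption is a constant (exponential) cause-specific hazard for each
transition.  This makes the hazard-ratio transform exact and leaves
three free hazards: progression `r_p`, death from PFS `r_d1`, death
from PD `r_d2`.

**Calibration.**  One printed quantity pins them down: the comparator
(KRd) arm's undiscounted restricted life-years, 3.52.  Three unknowns
and one target require two structural ratios, both exposed in the
configuration:

* `median_ttp_months = 26`, fixing `r_p = log(2)/26 ≈ 0.0267`/month — a
  typical progression-free median for modern triplet regimens in this
  population;
* `pd_mortality_ratio = 2`, i.e. `r_d2 = 2·r_d1` — post-progression
  excess mortality of the usual magnitude for relapsed myeloma.

The remaining mortality scale is found by Brent root finding on the
log-hazard over the bracket `[1e-6, 5]` per month, driving the cohort
engine's life-year total to the target within `1e-6`
(`calibrate_baseline()`); the calibration is deterministic and
idempotent, and parameter-recovery tests confirm a synthetic truth is
recovered to `1e-4`.

**Hazard-ratio application.**  The per-cycle transition matrix is
composed jointly from cause-specific hazards: staying in PFS has
probability `exp(−(r_p + r_d1))`, dying `1 − exp(−r_d1)`, progressing
the remainder, so the per-cause marginal equals the single-risk
conversion `1 − exp(−r)` and rows are exactly stochastic.  For DRd the
overall-survival ratio multiplies both death hazards and the
progression ratio multiplies `r_p`.  Because the published progression
effect is strictly a progression-*or-death* ratio, applying it to
progression only while the OS ratio covers death slightly double-counts
the survival benefit; the configuration switch
`apply_hr_pfs_to_death` applies it jointly instead (default off — the
default reproduces the published life-year gain more closely).

With these defaults the DRd arm yields `r
round(markov_cua()$arms$drd$total_ly, 3)` life-years against a
published 5.86 — agreement to about 1% without ever seeing a survival
curve, which is the main structural validation of the calibrated
exponential approach.

## Valuation of outcomes and costs

Cycle accruals use end-of-cycle occupancy with discount factor
`(1 + r)^(−t/12)` (costs 7.2%/year, QALYs 3%/year, life-years
undiscounted by default — the only combination consistent with the
published life-year figures).  A trapezoid half-cycle correction is
available (`half_cycle_correction`, default off: the published model
does not state one, and omitting it keeps the calibration convention
transparent).

Utilities: `u_PFS = 0.73`; the post-progression state is valued as the
PFS utility plus the progression disutility (0.73 − 0.054 = 0.676).
Adverse events subtract `p_AE · 0.049` per on-treatment cycle from the
progression-free occupancy and add an expected episode cost
`p_AE · (24.4 + 21.6)`; the per-cycle AE probabilities (DRd 0.011, KRd
0.026) are taken as published, since their derivation from overall AE
rates is not stated.

Drug costs follow the published calendars on a 28-day cycle ("once
weekly" = 4, "every 2 weeks" = 2, "every 4 weeks" = 1 administration
per cycle): daratumumab 4/4/2/2/2/2 then 1 per cycle through cycle 25
(35 administrations), carfilzomib 6 per cycle for 12 cycles then 4
through cycle 18 (96), dexamethasone 4 and lenalidomide 21 per cycle in
both arms.  Each administration is charged one unit of the published
unit price (the "400 mg per kilogram" dosing phrase is treated as an
erratum — weight-based vial counts cannot be reconciled with the
published cost totals; `units_per_administration` is configurable).
Monitoring (specialist visit + laboratory tests) accrues per cycle on
treatment and in off-treatment PFS; the PD cycle cost bundles visit,
laboratory tests, MRI, CT and radiotherapy ($58.48/cycle).  These
composition choices are configuration lists, not code.

**Cost-scale calibration.**  The published lifetime cost totals
($15,370 / $15,106) are not decomposed, and a bottom-up reconstruction
from unit prices cannot recover unpublished components (hospitalisation,
follow-up treatment mix).  Each arm therefore carries a single
multiplicative `cost_scale`, solved by linearity so the arm's
discounted lifetime cost equals its published total (default on).  This
preserves linearity in every unit price — the property the tornado and
price-threshold analyses rely on — and makes the incremental cost $264
exact at base case while leaving all *relative* price sensitivity
intact.

## Parameter uncertainty

Each uncertain parameter carries a mean, a 95% interval and a family
(beta for probabilities and utilities, gamma for costs, lognormal for
hazard ratios).  Only mean and interval are published, so the family is
fitted by matching the mean exactly and choosing the remaining
parameter by least squares on the 2.5%/97.5% quantiles (beta:
concentration; gamma: shape; lognormal: log-scale spread).  Disutilities
are fitted on their absolute value and negated on draw.  Parameters
published without intervals (demographics, cycle length, horizon,
discount rates) are fixed and excluded from all sensitivity analyses.

*One-way DSA* re-runs the deterministic pipeline at each parameter's
bounds (±20% would substitute where intervals are missing; all varied
parameters here have intervals), reporting incremental NMB as the
primary tornado metric with the ICUR alongside.  *Price-threshold
analysis* exploits the linearity of cost in any unit price and locates
by bisection (to $0.01) the price at which the ICUR meets the WTP, or
at which the incremental cost reaches zero (dominance).

*PSA* draws every varied parameter independently (no correlation
structure is published), re-running the pipeline per draw; 10,000
draws by default, seeded (default seed 20220810, the costing date).
Hazard-ratio and utility variation can each be switched off, since the
published analysis does not state whether they were varied.  Baseline
hazards and cost scales stay at their base-case calibration across
draws: the calibration target is a point estimate, and re-calibrating
per draw would absorb exactly the survival uncertainty the hazard-ratio
draws are meant to express.  Draws that would produce an invalid
post-progression utility are re-sampled (warned above 1%; in practice
none occur at the default inputs).  The per-draw evaluation is
vectorised across draws but is verified in the tests to agree with the
scalar pipeline to 1e-9, draw by draw.

## Budget impact

A five-year payer projection: population grows at the constant rate
implied by the first two published yearly populations (≈1.20%/year);
the myeloma pool is anchored at the published 2022 count (4,267) and
scaled with population (the published count is not exactly
incidence + prevalence × population — 4,327 — so the anchor mode is the
default and a rates mode is available); a death-rate adjustment
(3,456/4,267) and a 20% late-stage eligibility fraction yield the
treated pool; DRd uptake displaces KRd at 5/10/15/20/25% over years
1–5.  Per-patient annual costs are back-solved from the published
first-year scenario spending, so year 1 is exact by construction; later
years drift by <0.1% through the published table's own count rounding
(counts here are rounded half-to-even at each funnel stage).  No
discounting or inflation applies.  The five-year total comes to
$6,171,724 against a published $6,170,582 (the $6,192,000 mentioned
elsewhere in the source is inconsistent with its own table and is not
targeted).

## The microsimulation oracle and synthetic data

`simulate_patients()` replays the identical transition structure at
individual level on the cycle grid — deliberately discrete, so the
cohort engine and the microsimulation agree exactly in distribution,
not merely asymptotically.  At n = 100,000 the empirical occupancies
match the cohort trace within three binomial standard errors and the
empirical time-to-death distribution passes a Kolmogorov–Smirnov-style
check against the closed-form discrete survival curve (α = 0.01).
`generate_survival_dataset()` produces two-arm patient-level
progression/death tables under chosen hazard ratios; state-specific
rate estimators (and, as an independent check, Cox regression in a
single-risk setting) recover the generating ratios within Monte-Carlo
error.  A single seeded stream advanced cycle-wise across the cohort
(rather than per-patient substreams) keeps results exactly reproducible
for a given `(n, seed)` in this single-threaded implementation.

All randomness is confined to `run_psa()`, the microsimulation and
`dist_draw()`; every other computation is deterministic, and equal
seeds give byte-identical exports.

## What the defaults do and do not show

Problem sizes used throughout: 120 monthly cycles, 10,000 PSA draws,
100,000 microsimulated patients, 50,000 per arm for hazard-ratio
recovery — all run in seconds.  The synthetic machinery emulates
exponential event histories with the published effect sizes; it does
not emulate treatment discontinuation, subsequent-line sequencing,
covariate heterogeneity, informative censoring or non-proportional
hazards, so passing tests validate internal consistency and the
published-effect arithmetic, not those real-data phenomena.

## Known limitations

* **The published QALY totals are internally inconsistent.**  QALY/LY
  ratios of 1.56/5.86 and 1.28/3.52 imply mean utilities of ≈0.27 and
  ≈0.36, irreconcilable with the published utilities (0.73 PFS, 0.676
  PD) under any discounting.  The model does not force QALY
  calibration; its QALY totals (3.73/2.29, ΔQALY ≈ 1.44) follow from
  the published utilities.  Consequences: the base-case ICUR here
  (≈$183/QALY) sits well below the published $956/QALY, and the PSA
  acceptability at $1,290/QALY is ≈82% rather than the published 55% —
  with ΔQALY five times larger, far fewer draws can turn the
  incremental NMB negative.  The acceptability switch point does remain
  below the threshold (≈$206/QALY), agreeing with the published
  qualitative conclusion that DRd is cost-effective at the Iranian WTP.
* The published ICER of $472/LYG is arithmetically irreconcilable with
  its own increments (264/2.34 ≈ 113) and is not targeted.
* Baseline survival beyond the calibrated life-year target is an
  exponential extrapolation; any agreement with unpublished survival
  shapes is approximate.
* The cost build-up is calibrated at arm level; absolute (not relative)
  conclusions about individual cost components inherit that scaling.
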