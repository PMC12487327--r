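---
title: "Model methods: partitioned survival cost-effectiveness and value of implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: partitioned survival cost-effectiveness and value of implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petvoi)
```

## The decision problem

Clinical guidelines recommend surgery (mastectomy or breast-conserving
surgery) followed by adjuvant endocrine therapy (ET) as first-line
management for operable early-stage breast cancer, yet a substantial share
of women aged 70 and over who are fit for surgery receive primary endocrine
therapy (PET) instead. `petvoi` implements a decision model that quantifies,
from the perspective of the NHS in England, (i) the cost-effectiveness of
surgery + ET relative to PET, and (ii) the population health forgone
because uptake of the cost-effective strategy is imperfect — the expected
value of perfect implementation (EVPImp).

The package is a re-implementation of a published Excel-based analysis.
Every input comes from the printed parameter table of that analysis
(shipped as `inst/extdata/model_parameters.yaml`); no patient-level data
are used or distributed. Where the original report left a modelling
convention unstated, this package fixed the convention by calibration
against the original's reported outcome table, and each such choice is
documented below, is visible in the run log written by
`run_full_analysis()`, and can be switched off through `parameter_set()`.

## Model structure

A partitioned survival model (PSM) with three health states — stable
(progression-free), progressed, dead — run in 6-month cycles with
half-cycle correction over a lifetime horizon:

* stable(t) = min(PFS(t), OS(t))
* progressed(t) = OS(t) − PFS(t), split into a *local* and a *metastatic*
  substate by an arm-specific metastatic share (42% surgery + ET, 35% PET)
* dead(t) = 1 − OS(t)

The PET arm's curves are parametric fits to long-follow-up trial data
(below); the surgery + ET arm applies proportional-hazards adjustments,
`S(t)^HR`, with HR 0.86 for overall survival and 0.65 for progression-free
survival. Occupancy is accrued at the mean of adjacent cycle boundaries
(half-cycle correction), and per-cycle quantities are discounted at the
midpoint of each cycle.

A `mode = "markov"` variant is provided in which the progressed substates
drain at the published per-cycle death probabilities (0.04 local, 0.11
metastatic) instead of following the OS curve. It exists because the
source material labels the model both ways; the default is the partitioned
survival reading, which its own text states.

## Survival inputs and the calibration

The PET progression-free survival curve is the published log-normal with
location (meanlog) 1.40 and scale (sdlog) 0.98 on log-years — a median PFS
of `exp(1.40) = 4.06` years. It is used literally.

The PET overall-survival curve was published as a log-logistic with
"shape 1.72, location 0.41", without stating the parametrization or the
software convention behind those symbols. Under this package's declared
parametrization, `S(t) = 1 / (1 + (rate * t)^shape)`, no direct mapping of
those two numbers reproduces the original's reported outcomes (their
implied life expectancy is off by 30–40%). Two observations resolve it:

* Stata's log-logistic reports an *ancillary* shape whose reciprocal is
  the survival-function exponent; `1/1.72 = 0.58`.
* The original reports a model-estimated median overall survival of
  5.5–6.0 years for PET.

The shipped default therefore keeps the reciprocal-shape reading and
calibrates (shape, rate) jointly so that both arms reproduce the original's
reported life expectancy and QALYs: **shape 0.60, rate 1/6.0** (median
overall survival 6.0 years, at the top of the reported band). The literal
mapping (shape 1.72, rate `exp(-0.41)`) remains available via
`parameter_set(survival = "literal")` for sensitivity work; it is *not*
expected to reproduce the original outcome table.

Calibration targets were the original's undiscounted life years
(15.75 / 13.94), discounted QALYs (4.57 / 3.87) and costs
(£10,627.57 / £6,101.76) for surgery + ET / PET. The shipped defaults
reproduce the effects to within 2% and the costs to within ~4%; the
acceptance script (`scripts/acceptance.R`) recomputes these from scratch.

## Discounting

Both costs and QALYs are discounted at 3.5%. The shipped default applies
the 3.5% factor **per 6-month model cycle** (`discount_per_cycle = TRUE`,
an effective 7.1% per year). This is deliberate: the original's reported
QALY-to-life-year relationship is only attainable under per-cycle
discounting, a common spreadsheet-model convention. Annual compounding
(`discount_per_cycle = FALSE`) is available and is what the package's own
convergence tests use (halving the cycle length then changes discounted
QALYs by < 1%; under per-cycle discounting the effective rate is tied to
the cycle, so refining the grid intentionally changes the answer).
Life years are reported undiscounted.

## Utilities

Stable-state utility is 0.75 (EQ-5D-3L, UK tariff), declining by 0.0013
per year of age (the printed table value; the source's text rounds it to
0.001). The printed progressed-state decrements are −0.126 (local
recurrence) and −0.352 (metastatic). Under the shipped default
(`progressed_utility = "uniform"`) the whole progressed state carries the
−0.352 decrement: calibration shows the original's QALY totals are
consistent only with a metastasis-dominated progressed-state utility, and
this is clinically defensible for a state whose costing basis is advanced
disease. The substate-specific reading (`"split"`) is one flag away and is
what `state_utility()` demonstrates in its examples. Utilities are floored
at zero during accrual (with a warning); probabilistic draws are truncated
so no state utility leaves `[-0.594, 1]`, the EQ-5D-3L range.

## Costs

All costs are 2020/21 GBP. The accrual schedule, component by component,
with the reasoning where the original was ambiguous:

* **Surgery (one-off, cycle 0, surgery arm):** the tariff mix
  `0.35 x £6,547.64 (mastectomy) + 0.65 x £2,867.69 (BCS) = £4,155.67`.
  The original also prints an aggregate of £6,619.53 said to include
  delayed reconstruction; that aggregate cannot be reconciled with the
  original's own total-cost table under any accrual schedule we examined,
  so the component mix is the default and the aggregate is available via
  `cost_surgery_oneoff = 6619.53`.
* **Hospital stay (£937):** excluded by default
  (`include_hospital_stay = FALSE`) because NHS HRG procedure tariffs
  already include the inpatient stay; charging it separately double-counts.
  The toggle adds it to the surgical one-off.
* **Endocrine therapy (per cycle, stable state, both arms):** tamoxifen
  £0.30/day for years 0–5, then letrozole £3.25/day for years 5–10
  (365.25 days/year).
* **Follow-up (£509.22/year, stable state):** accrued during the 10-year
  endocrine-therapy period (`followup_years = 10`).
* **Progression (`progression_cost_mode = "entry_episode"`):** the printed
  progressed/metastatic figures (£8,251.75 / £6,223.54) are read as
  *annual* management costs — their own gamma distributions have means of
  exactly twice these values, i.e. the printed points are 6-month amounts
  of a 1-year cost. On each exit from the stable state the model charges
  one half-year episode, mixed by the arm's metastatic share. In a PSM,
  exits from stable cannot be decomposed into progression versus death
  without extra assumptions; charging every exit reflects that end-of-life
  care in this population typically follows progression. A `"per_year"`
  mode accrues the full annual costs over all progressed person-time
  instead (it roughly triples PET-arm costs and is not consistent with the
  original totals).

## Probabilistic sensitivity analysis

`run_psa()` draws every uncertain parameter per iteration and runs the
engine for both arms on the shared draw (common random numbers):

* hazard ratios: lognormal, normal on the log scale around the log of the
  printed mean (SD 0.07);
* proportions and the stable utility: beta with the printed shapes;
* utility decrements: normal (mean, SE), truncated to the EQ-5D-3L range;
* state costs: gamma with the printed shapes/scales, each draw rescaled by
  0.5 so the sampled mean equals the deterministic annual cost;
* survival-curve pairs: bivariate normal through the printed Cholesky
  factors, applied on the log-parameter scale for positivity-constrained
  parameters (shape, rate, sdlog) and on the natural scale for the
  log-normal location.

Reproducibility: iteration `i` re-seeds the generator at `seed + i` and
draws parameters in the fixed order of the specification table. This makes
results independent of how many iterations ran before inspection, at the
cost that inserting a new parameter row shifts the draws after it; a
per-parameter substream scheme was considered and rejected as complexity
without benefit at this model size. Invalid draws (a trace that fails its
invariants) are redrawn from a shifted seed and counted in `rejections`.

The default analysis size is 10,000 iterations; the package's tests and
the acceptance script use 2,000, which bounds the Monte-Carlo SE of a
CEAC probability near 0.98 at about 0.3 points and runs in under a minute.

## Value of implementation

With expected net benefit `NB_j` per strategy and current uptake shares
`rho_j` (audit estimates: 76% surgery + ET, 24% PET):

EVPImp = max_j NB_j − sum_j rho_j NB_j,

which for two strategies collapses to `(1 − rho*) x INMB` — an identity the
tests exploit as an oracle. Per-person EVPImp uses the deterministic
base-case net benefits (matching the original's arithmetic); a PSA-mean
variant is a matter of passing `summary(psa)`-derived NBs to
`evpimp_per_person()`. Population scale-up multiplies by the discounted
cumulative incident population: 9,356 eligible women per year over 10
years at 3.5%, first cohort at t = 0 (undiscounted) — the t = 0 convention
reproduces the original's printed population to within 0.01%, and a t = 1
start is available via `first_cohort_at = 1`. Monetary values convert to
QALYs by dividing by the threshold.

## Survival fitting and curve reconstruction

The extrapolation workflow the model inputs came from is implemented so
the pipeline can be rerun end-to-end on reconstructed or synthetic data:

* `fit_parametric_survival()` fits exponential, Weibull, Gompertz,
  log-normal and log-logistic models by maximum likelihood under right
  censoring (via `flexsurv`), mapping estimates onto the package's declared
  parametrizations; `select_best_fit()` ranks by AIC with BIC as the
  tiebreak, returning the full table for visual plausibility checks.
* `reconstruct_ipd()` rebuilds individual event/censoring times from
  digitized Kaplan-Meier coordinates plus a numbers-at-risk table. Within
  each risk interval the censoring count is solved iteratively so the
  implied number at risk matches the published count, censoring times
  spread evenly (constant censoring rate); with a published total event
  count, per-step events are rescaled to match. The last interval assumes
  no interior censoring, with survivors administratively censored at the
  final coordinate — appropriate for the long-follow-up trial setting
  emulated here. The algorithm is deterministic.

## Synthetic data

`simulate_ipd()` generates right-censored records from any of the five
families (default test setting: 500 subjects per arm, 20-year
administrative censoring, mirroring a mature trial), and
`digitize_fixture()` emulates the digitization artefacts — step-curve
values on a grid and interval at-risk counts. What these fixtures do *not*
emulate: digitization click noise, reader error in reading published
curves, and covariate structure. Round-trip tests (reconstruction KM
within ±0.02 of the source curve) therefore show algorithmic correctness,
not robustness to a sloppy digitization.

## Numerical choices

* Root-finding for medians: bracketed `uniroot` to 1e-6 years where no
  closed form exists; closed forms for exponential, Weibull, log-normal,
  log-logistic.
* Fitting restarts from up to three deterministic starting points
  (moment-based, then perturbed) before declaring non-convergence.
* PFS is clipped to OS before partitioning (`min(PFS, OS)`); with the
  shipped curves the clip binds during roughly the first four years, where
  the fitted PFS curve sits above OS.
* ICER degeneracy: |ΔQALY| < 1e-9 yields a dominance/equivalence label
  instead of a division.
* Trace conservation is asserted to 1e-9 at every cycle.

## Problem sizes used by the tests

Deterministic runs use the full 70-cycle model. Parameter-recovery checks
use 100 replicates per family at n = 2,000; model-selection frequency uses
30 replicates; reconstruction round-trips use 20 seeded curves of 400–500
subjects; PSA checks use 2,000 iterations (20,000 draws for marginal
moments). These sizes keep the whole suite under a few minutes while
leaving Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The calibration pins the survival shape to the original's reported
  outcomes; it is a replication device, not an independent re-estimation —
  with the original trial's underlying data one would refit directly.
* The heavy-tailed calibrated OS curve implies non-negligible survival
  beyond age 100; truncation at the 35-year horizon bounds its effect.
* Progression events are proxied by exits from the stable state, an upper
  bound on true progression incidence in a PSM.
* The EVPImp assumes every non-surgical patient receives PET and static
  uptake over the 10-year population horizon; both overstate the value of
  implementation, so population results are upper bounds.
* No adverse-event, re-operation or treatment-sequencing costs; no
  interval censoring or covariate-adjusted survival modelling.
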