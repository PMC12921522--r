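---
title: "Methods: a cost-utility Markov model of early versus delayed belimumab in SLE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cost-utility Markov model of early versus delayed belimumab in SLE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lupuscea)
```

## The decision problem

Belimumab, the first biologic approved for systemic lupus erythematosus
(SLE), is usually reimbursed only after standard immunosuppressants fail.
Accumulating cohort evidence suggests that initiating it early (within
about two years of diagnosis) produces faster, more durable SRI-4
responses. `lupuscea` implements a cost-utility analysis of that question
from a US payer perspective: a six-state Markov cohort model compares an
*early* and a *delayed* initiation strategy over a 15-year horizon of
monthly cycles, accumulating discounted costs (2024 USD) and
quality-adjusted life-years (QALYs), and summarising the comparison as an
incremental cost-effectiveness ratio (ICER) and an incremental net
monetary benefit (INMB) at a willingness-to-pay of $50,000/QALY.

## Model structure

The six reported health states are **pretreatment**, **complete
response** (SRI-4 met), **partial response** (improved, SRI-4 not met),
**nonresponse**, **no treatment**, and absorbing **death**. The whole
cohort starts in pretreatment on belimumab and, after a four-month
induction period, splits into the three response states. Transitions
follow a bidirectional stepwise structure (complete ↔ partial ↔
nonresponse). Nonresponders may restart induction, stop biologic therapy,
or switch to anifrolumab; patients off treatment who suffer a severe
flare initiate anifrolumab.

Because a six-state Markov chain cannot remember which biologic a patient
is on after a switch, the engine expands the state space internally to
health state × drug context (belimumab / anifrolumab / off treatment) —
eight living sub-states plus death — and collapses back to the six
reported states for output (`collapse_trace()`). Switch and flare entries
into anifrolumab use trial-derived response probabilities attenuated for
biologic-experienced patients.

Two deliberately simple conventions close gaps the reported design leaves
open:

* **Death-first competing risks.** Each cycle the age/sex mortality
  probability is applied from every living state first, and the remaining
  probability mass follows the disease transitions, rescaled
  proportionally. The order is explicit so the row-stochasticity of every
  transition matrix is exact by construction.
* **Re-induction without cycle memory.** The initial induction is timed
  on the global clock (the cohort holds in pretreatment for exactly four
  cycles, then splits). Patients who later *restart* re-enter
  pretreatment, where the split is applied at a constant per-cycle rate of
  1/(induction length) — a geometric approximation whose mean dwell time
  equals the induction period.

The two strategies share one parameter set and one code path. They differ
only through declared parameters: the early arm applies the SRI-4
response odds ratio to the complete-response odds of the induction split
(partial/nonresponse mass is rescaled proportionally), and carries a
+10 mg/day baseline prednisone offset while in pretreatment. With the
odds ratio at 1 and the offset at 0 the arms are bit-identical — a
property the test suite asserts — so no hidden code path can generate an
artefactual arm difference.

## Mortality

All-cause mortality uses an annual life table adjusted by age- and
sex-specific standardized mortality ratios (SMRs), as observed in
population-based SLE cohorts: per sex, the annual death probability is
converted to a hazard, multiplied by the SMR for the current age band,
blended across sexes at the hazard scale using the cohort's 91.2% female
mix, and converted to a monthly probability. Ages are floored to whole
years for lookup. The default SMR map declines with age (≈3 below 40 to
≈1.4 at 60+ for women), reflecting the strong relative excess mortality
of young SLE patients; a single log-normal multiplier carries its joint
uncertainty in probabilistic analysis while the life table itself is held
fixed.

The shipped life table is synthetic: Gompertz–Makeham mortality
`qx(age) = 1 − exp(−(A + B·e^(c·age)))` per sex, with parameters chosen
to give US-like adult magnitudes (e.g. female q40 ≈ 0.001, male q40 ≈
0.0015) and female rates below male rates at every age, covering ages
0–100 so that any horizon up to the lifetime cap fits inside the table.
`load_life_table()` accepts a real life table CSV (`age,sex,qx`) for
users who have one.

## Utilities

State utilities are anchored at the complete-response level with strictly
positive decrements for partial response and nonresponse, so the ordering
nonresponse ≤ partial ≤ complete survives every probabilistic draw by
construction. A piecewise-constant multiplicative time trend (anchored at
years 0/2/5/10) emulates the gradual EQ-5D improvement seen in incident
SLE cohorts. A glucocorticoid disutility of −0.005 EQ-5D per mg/day of
prednisone equivalent is applied to each state's maintenance dose
(responders taper, nonresponders stay high); the decrement is applied to
the absolute dose relative to a zero reference. An alternative reading —
applying the decrement to the *change* in dose between cycles — would
reward tapering transiently rather than penalise sustained exposure; we
use the absolute-dose form because it makes steady-state utilities
well-defined, and note that the linearity property (Δutility = 0.005 ×
Δdose before clamping to the EQ-5D range [−0.594, 1]) holds either way.
The early arm's +10 mg/day baseline offset applies only in pretreatment,
where tapering has not yet begun.

## Costs

Costs are stratified by health state from a payer perspective, in 2024
USD, discounted (with QALYs) at 3% per year.

* **Drug acquisition** uses wholesale acquisition cost (WAC) per vial
  with whole-vial wastage: belimumab 10 mg/kg (400 mg vials, so a 70 kg
  patient needs ⌈700/400⌉ = 2 vials), anifrolumab a fixed 300 mg vial.
  Both are given every 4 weeks; the 4-week schedule is mapped onto
  monthly cycles at 13/12 infusions per month in expectation, keeping
  the monthly Markov clock exact without modelling week-level timing. The
  first model month carries belimumab's two loading doses (weeks 0 and
  2). A single `biologic_cost_scalar` multiplies both biologics'
  acquisition costs; it absorbs administration and schedule costs not
  itemized elsewhere and is one of the calibration's free parameters.
* **Secondary medical costs** (hospitalisations, outpatient and
  emergency care) are monthly, state-stratified — nonresponse highest,
  complete response lowest — equal across biologics, and decline
  modestly over time after initiation (piecewise-constant trend),
  consistent with claims-based cost trajectories.

QALYs and costs are credited with the state occupied at the beginning of
each cycle, without half-cycle correction by default (the underlying
decision-tree software's convention is not reported); a
`half_cycle_correction` flag averages adjacent occupancy rows for users
who prefer it.

## The parameter ledger

Every numeric input lives in a single validated ledger
(`generate_default_ledger()`, or YAML via `load_ledger()`): base value,
one-way bounds (defaulting to ±30% of base when no published range is
available, on the parameter's natural scale — odds ratios on the OR
scale), a sampling distribution, units, and a provenance note. The
distribution families follow the analysis' assignment rule — beta for
probabilities and utilities, log-normal for costs and odds ratios,
normal for continuous clinical parameters — and `validate_ledger()`
rejects mismatches. Moment-matched specs store only a standard error and
re-derive their shape parameters from the *current* base value at
sampling time, so recalibration automatically re-centres the
distributions. Parameters are drawn independently (no correlation is
modelled, matching the stated design of independent prespecified
distributions); out-of-support draws of probability-type quantities are
clipped and counted, never silently accepted. The engine's required
parameter names are enumerated from code (`required_parameters()`), so
the validator cannot drift from the engine.

The supplementary table holding the original study's concrete inputs is
not reprinted in its main text. The ledger therefore distinguishes three
provenance labels: `"printed"` (set exactly from the main text: 3%
discounting, $50,000/QALY, the −0.005/mg decrement, the 1.08–3.47
odds-ratio range, 15%/60% biosimilar discounts, the +10 mg/day early-arm
prednisone offset, the 4-month induction, start age 41, 91.2% female),
`"synthetic"` (plausible clinical magnitudes chosen once), and
`"synthetic-calibrated"` (pinned by calibration, below). Monthly disease
transitions are deliberately slow (fractions of a percent to a few
percent per month), consistent with the durable responses seen in the
13-year belimumab continuation experience; restart after discontinuation
is comparatively frequent (6%/month among nonresponders), making
retreatment — whose response split is arm-specific — the mechanism that
sustains the arms' contrast at long horizons.

## Calibration

`calibrate_to_base_case()` pins four free parameters to the four printed
base-case totals (early $1,910,438.61 / 7.68 QALYs; delayed
$2,036,775.73 / 7.38 QALYs) by bounded L-BFGS-B minimisation of the sum
of squared *relative* residuals, so costs (~10^6) and QALYs (~10^0)
weigh equally. The free parameters each dominantly drive one target:

| knob | target it drives |
|---|---|
| `or_sri4_early` (within the printed 1.08–3.47 range) | QALY gap |
| `u_complete` | QALY level |
| `cost_nr` | delayed-arm cost |
| `biologic_cost_scalar` | early-arm cost |

The odds ratio is used as the gap knob rather than the delayed-arm
response probability because the induction split's *level* barely moves
the between-arm QALY difference while the odds ratio moves it strongly;
the calibrated value (≈2.66) sits inside the printed one-way range. The
start point is the ledger's current base values and the routine is
deterministic; the shipped ledger already stores the calibrated solution,
so the shipped calibration verifies convergence in one objective
evaluation (relative residuals ~10^−7, well inside the 0.005 tolerance)
and any edited ledger re-converges from its own values. Calibrated values
are constrained to their declared bounds.

## Outputs and sensitivity machinery

* `run_base_case()` / `compare_strategies()`: discounted totals, ICER,
  INMB, dominance label, per-cycle audit trail whose column sums
  reproduce the totals exactly.
* `run_psa()`: Monte Carlo propagation (default 10,000 simulations). One
  shared parameter draw is applied to both arms per simulation — the arms
  differ by declared effect parameters only, so independent draws per arm
  would inflate the incremental variance. Per-draw substream seeds derive
  from one master seed, making results independent of evaluation order.
  95% uncertainty intervals use the type-7 (linear interpolation)
  percentile definition, fixed and documented. Quadrant proportions on
  the cost-effectiveness plane, the fraction of draws favouring each
  strategy (INMB ties split 0.5/0.5), and the acceptability curve are
  reported.
* `one_way()` / `tornado_analysis()`: deterministic one-way analysis over
  every bounded ledger parameter, bars sorted by INMB width.
* `horizon_sweep()`: full reruns across horizons (1–25 years).
* `biosimilar_scenario()`: WAC multipliers in (0, 1] applied to both
  biologics from a configurable entry year; efficacy, utility and
  secondary-cost parameters are untouched by construction.

Negative ICERs are reported numerically but always alongside the
dominance label, since a negative ratio is not comparable to a
willingness-to-pay threshold; decision logic uses INMB throughout.

## What the synthetic inputs can and cannot show

The generator reproduces the *structure* of the original evidence base —
distribution families, parameter roles, printed constants — and the
calibration reproduces its printed base-case totals and qualitative
sensitivity patterns (dominance of early initiation; INMB rising with
horizon and with the response odds ratio; deeper biosimilar discounts
raising INMB; pricing scenarios acting through costs only). It does not
recover the study's actual inputs: dispersion parameters are guesses of
plausible magnitude, so probabilistic uncertainty intervals, quadrant
percentages and exact one-way INMB endpoints are *not* comparable to the
published ones, and calibrated knobs (e.g. the ≈$33.7k/month nonresponse
secondary cost) are best read as "whatever absorbs everything the model
does not itemize". Passing tests therefore certify the engine's
arithmetic and the calibrated reproduction, not the literature-derived
values themselves. One known tension: with this model's front-loaded
increments, a 5% discount rate lowers the INMB relative to 0%, whereas
the original reports the opposite ordering — the one-way analysis runs
both bounds and reports the direction rather than asserting it.

## Numerical choices

Problem sizes and tolerances used throughout: 180 monthly cycles (181
trace rows) for the base case; transition-matrix rows sum to 1 within
1e-10 and trace rows within 1e-9; the cohort iteration is checked against
a closed-form eigendecomposition matrix power at 1e-12 on a constant
3-state reduction; moment-fit round trips hold to 1e-10 (using
`log1p`/`expm1` where catastrophic cancellation would otherwise bite at
small coefficients of variation). Ties at INMB exactly 0 are split
evenly; cost-effectiveness-plane boundary points go to the positive-QALY
side (the origin to the southeast). The lifetime horizon is
operationalised as run-to-age-100, the end of the synthetic life table.

## Limitations

Organ damage is not a discrete state (its QALY effect is carried
indirectly by prednisone trajectories and the glucocorticoid decrement);
the model is a cohort simulation, not a microsimulation, so state costs
and utilities apply uniformly within a state; treatment discontinuation
for sustained remission is not modelled; parameter correlation is not
modelled; and hydroxychloroquine co-therapy is not represented. All are
deliberate scope choices that mirror the reported design.
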