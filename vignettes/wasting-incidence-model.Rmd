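---
title: "A Markov cohort model for child wasting incidence and caseload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for child wasting incidence and caseload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wastingMarkov)
```

## The problem

Humanitarian nutrition programs plan treatment capacity for the coming
year from an annual *caseload*: the prevalent cases of wasting at the
start of the year plus the incident cases expected over the year.
Incidence cannot be observed directly — following untreated wasted
children is ethically impossible — so it is back-calculated from
cross-sectional prevalence through

\[
\mathrm{Incidence} = \mathrm{prevalence} \times \frac{12}{\mathrm{duration\ of\ episode}}
  = \mathrm{prevalence} \times k ,
\]

where the *incidence correction factor* \(k = 12/\text{duration}\). The
conventional global value is a 7.5-month mean episode duration
(\(k = 1.6\)), derived from 1980s cohort studies. Every study that has
re-estimated \(k\) in a specific context has found it substantially
larger, i.e. caseloads substantially under-planned. This package
re-derives context-specific \(k\) values for moderate and severe wasting
with a discrete-time Markov cohort model, packaged with the Lahj
governorate (Yemen) configuration, and provides the surrounding pipeline:
parameter estimation from program records, calibration, caseload
reporting, one-way sensitivity analysis and a synthetic data generator.

## The model

Eight mutually exclusive states, in the canonical order used everywhere
in the package:

| state | meaning |
|---|---|
| `Healthy` | not wasted (includes children in treatment > 1 month, who no longer meet the anthropometric case definition) |
| `ModeratelyWasted` | moderate wasting (−3 < WHZ < −2), not in treatment |
| `SeverelyWasted` | severe wasting (WHZ < −3) without complications, not in treatment |
| `SeverelyWastedComplicated` | severe wasting with medical complications, not in treatment |
| `TreatmentM` | enrolled in a TSFP (moderate tier) |
| `TreatmentS` | enrolled in an OTP (uncomplicated severe tier) |
| `TreatmentSC` | enrolled in a TFC (inpatient, complicated severe) |
| `Deceased` | absorbing |

Transitions happen once per month. Structural assumptions, enforced as
exact zeros in every constructed matrix (`allowed_transitions()`):
a child must pass through moderate wasting before becoming severely
wasted; a severely wasted child cannot return to `Healthy` without first
improving to moderate or being treated; treatment may end in cure,
default, non-response, referral or death, with default/non-response
returning the child to the wasting state it came from; `Deceased` is
absorbing.

The model is a deterministic *expected-count* cohort model: censuses are
real-valued expectations, not sampled individuals, and advancing one
month is a vector–matrix product (`step_census()`, `simulate_cohort()`).
A stochastic individual-level mode is out of scope.

### Transition probabilities

Treatment-admission probabilities (`ModeratelyWasted->TreatmentM`,
`SeverelyWasted->TreatmentS`, `SeverelyWastedComplicated->TreatmentSC`)
are time-varying: admissions fluctuate strongly month to month, so one
value per simulated month is supplied (`build_matrix_sequence()`). All
other probabilities are stationary: treatment outcomes pooled over
monthly program records (`outcome_probabilities()`), under-five
mortality from survey data, and literature estimates for spontaneous
recovery, improvement from severe to moderate, and untreated case
fatality. The packaged Lahj values are in
`system.file("extdata", "lahj.yaml", package = "wastingMarkov")`.

**Self-transitions are always computed as exact complements** of each
row's off-diagonal sum, never taken from published remain-in-state
constants. This guarantees row-stochasticity by construction (row sums
equal 1 exactly; the test suite checks 1e-9). The published constants
are kept only for `printed_complement_diagnostic()`, which reconstructs
1 within 5e-3 for every row except `SeverelyWasted`: its published
constant (0.0724) conflicts with its published off-diagonal rates, which
sum to 0.11038. The source material does not say which is authoritative;
the complement rule uses the off-diagonal rates and the diagnostic
surfaces the discrepancy.

### Initial state distribution

`build_initial_census()` reconstructs the month-0 census from a combined
survey summary and program enrolment figures. A cross-sectional survey
cannot distinguish untreated wasted children from those recently
admitted to treatment: children enrolled for at least a month have
regained enough weight to fall outside the anthropometric case
definition, so the surveyed prevalence is interpreted as untreated cases
*plus* the past month's admissions, and both are placed in the untreated
state. Treatment states start with enrolment minus the last month's
admissions; untreated severe cases are split into uncomplicated and
complicated in the ratio of outpatient (OTP) to inpatient (TFC)
admissions (`complication_split()`); `TreatmentSC` and `Deceased` start
at zero (inpatient stays last under a month). The packaged Lahj census
(167,907 children) reproduces this construction.

### Observed prevalence

For the same reason, the model quantity compared against a follow-up
survey is not the raw untreated-state count but
`observed_prevalence()`: the untreated count at month \(m\) plus the
inflow into the tier's treatment state during month \(m\). Inflows are
tracked explicitly per month in the trajectory object rather than by
adding extra states.

## Calibration

The two incidence probabilities — `Healthy->ModeratelyWasted` (moderate
incidence, \(p_{HM}\)) and `ModeratelyWasted->SeverelyWasted`
(progression, i.e. severe incidence, \(p_{MS}\)) — are unknown. Each is
found by requiring the simulated observed prevalence at the validation
month (month 14: August 2018 to October 2019 for Lahj) to match the
follow-up survey count.

`forward_prevalence()` is strictly increasing in the candidate
probability (more incidence always means more observed prevalence, all
else fixed — property-tested on random feasible configurations), so
`calibrate_incidence()` uses plain bisection on the bracket
\([0, p_{\max}]\), where \(p_{\max}\) is the largest candidate keeping
the affected matrix row feasible in every month. Bisection was chosen
over derivative-based methods because monotonicity is guaranteed but
smoothness in the time-varying admission inputs is not. The stopping
rule is on the *achieved prevalence*: |achieved − target| ≤ 1e-3
expected children (default), at most 200 iterations. Degenerate inputs
are handled explicitly: a target matching the zero-candidate endpoint
returns probability 0 (with infinite episode duration), and targets
outside the bracket raise an error reporting both endpoints.

### Ordering and the fixed point

Severe incidence is calibrated first and then frozen for the moderate
calibration, because the moderate prevalence depends directly on the
progression drain and on recovery inflow from the severe pool; the
interface makes the reverse order impossible (a moderate calibration
without a severe incidence in the stationary rates is an error). The
severe side, however, is not independent of the moderate one either:
over a 14-month horizon the moderate pool that progression draws from
is replenished almost entirely by the unknown moderate incidence. With
\(p_{HM}\) absent, the moderate pool drains within months and the entire
attainable range of the severe forward map on the Lahj configuration is
on the order of a hundred children — far below any realistic target, so
a single severe-then-moderate pass cannot even bracket.
`sequential_calibration()` therefore iterates the severe-first pair to a
fixed point: bootstrap \(p_{HM}\) by a moderate calibration with
progression set to 0, then alternate severe and moderate calibrations
(each freezing the other tier's latest estimate) until neither
probability moves by more than 1e-6 relative. Convergence is geometric
in practice (typically 10–15 rounds), and on noise-free synthetic
scenarios the fixed point recovers the generating probabilities to well
within 0.1% — the identifiability check the test suite runs over 20
seeds.

### From calibration to k, duration and caseload

Monthly incident cases are candidate × source-pool at each month start
(`Healthy` for moderate, `ModeratelyWasted` for severe); the annual
count sums simulation months 1–12. Then

* \(k\) = annual incident cases / baseline prevalence, with the
  baseline taken as the *surveyed* untreated count at month 0 (19,224
  moderate; 4,199 severe in Lahj) — the denominator month is not
  specified in the source material, and month 0 is the choice that
  reproduces the published severe caseload arithmetic;
* duration = \(12/k\) months;
* annual caseload = prevalence × (1 + \(k\)) (`annual_caseload()`), and
  `percent_increase()` compares the context-specific caseload with the
  conventional \(k = 1.6\) one.

Two documented inconsistencies in the published Lahj figures are worth
noting. First, the published moderate context-specific caseload (67,891)
is *not* the value of prevalence × (1 + k) with the published k = 2.59
(which gives ≈ 69,014); whatever summation produced it was not stated,
so this package implements the formula that is consistent with the
severe row. Second, the published October 2019 validation counts list
3,733 children against the moderate label and 21,358 against the severe
label, the reverse of every other quantity's ordering (August 2018:
moderate 19,224 ≫ severe 4,199); the packaged configuration treats the
labels as interchanged (severe target 3,733, moderate target 21,358).

`progression_fraction()` reports the share of moderately wasted
children who progress to severe wasting over the run. Its denominator
is not defined in the source material; this package uses cumulative
ever-moderate mass (initial moderate pool plus all inflows into
`ModeratelyWasted`), so the number should be read as approximate.

## Sensitivity analysis

`one_way_sweep()` scales one transition probability through multipliers
of its base value — default grid \(\{0.5, 0.75, 1.0, 1.25, 1.5\}\),
spanning the conventional 50–150% range; the grid itself is this
package's choice — and re-runs the single-tier calibration at each
point with the other tier's incidence frozen at its base calibrated
value. Multiplier 1.0 is always included and reproduces the unperturbed
calibration exactly. Perturbations that push a probability above 1 are
skipped with a warning; admission-series multipliers scale every monthly
value and are clamped at row feasibility (also with a warning).
`rank_impacts()` orders parameters by the spread (max − min) of the
recalibrated incidence, ties broken alphabetically; structurally zero
rates have exactly zero impact. Sweeps contain no randomness: given the
same inputs they are byte-identical.

## The synthetic data generator

The real monthly program records behind the Lahj analysis are not
public, so `generate_scenario()` emulates them. It simulates the true
model forward under known incidence probabilities and seasonal
admission series, then derives what a program would record:

* **Admission probabilities**: one 12-month sinusoid per program,
  centred on the midpoint of the program's observed monthly range
  (OTP [0.200, 0.678], TSFP [0.0529, 0.176], TFC [0.0, 0.229]) with
  seeded random phase and Gaussian jitter, clipped so every month stays
  inside the range. Default amplitude 0.6 of the half-range — the
  source records are described only as varying "considerably" month to
  month, so a strong but not range-filling seasonal swing was chosen
  once as the study condition.
* **Records**: integer monthly admissions and outcome counts per
  program, rounded (round-half-even) from the expected flows, with
  outcome sums trimmed to never exceed enrolment.
* **Surveys**: start and end survey summaries; the end prevalence is
  the trajectory's observed prevalence (plus optional truncated
  Gaussian noise on the proportion, default off).
* **Truth**: the generating probabilities and full trajectory, kept for
  recovery checks.

Default conditions: Lahj population (167,907) and initial distribution,
14-month horizon, true \(p_{MS} = 0.06\) and \(p_{HM} = 0.032\) — the
order of magnitude implied by the published context-specific \(k\)
values against the Lahj pools (annual severe incident cases ≈ 3 × the
severe pool require roughly 0.06 × the moderate pool per month, and
analogously for the moderate tier).

What the generator does *not* emulate — and hence what passing
recovery tests do not show about real data: survey sampling error and
design effects, displacement-driven population change, reporting gaps
and double counting in program records, seasonally varying mortality or
recovery, and case-definition drift between MUAC and WHZ screening. The
admission-probability denominator deserves a special caveat: neither the
eligible pool used to normalise real admission counts nor the published
ranges' normalisation is documented anywhere, so this package defines
the admission probability as admissions / expected untreated source pool
at the month start (the only state the admission arrow leaves from), and
the synthetic bundles derive their "records-based" admission series with
the generator's own pools. Real records would require an external pool
estimate, making this the most model-circular input of the pipeline.

## Numerical choices

* Row sums: exact by complement construction; validated at 1e-9.
* Conservation of total population: 1e-6 relative over ≤ 24 steps.
* Bisection: tolerance 1e-3 expected children on the achieved
  prevalence, max 200 iterations; fixed-point relaxation tolerance 1e-6
  relative on both probabilities, max 50 rounds.
* Round-half-even integerisation of synthetic records; residual
  discrepancies under one child/month are tolerated by the consistency
  checks.
* Probabilities are accepted at the closed bounds [0, 1]; infeasible
  rows fail fast naming the row.

The test suite runs the full pipeline at the real Lahj problem size
(1.7e5 children, 14 months), 100 random configurations for the
monotonicity property, and 20 seeded synthetic scenarios for parameter
recovery; these sizes keep the whole suite under a few minutes while
leaving the statistical checks meaningful.

## Worked example

```{r example, eval = FALSE}
lahj <- lahj_calibration_inputs(seed = 1)
fit <- sequential_calibration(lahj$inputs, lahj$targets$severe,
                              lahj$targets$moderate)
fit$severe
caseload_report("severe", 4199, k_context = fit$severe$k)
```

Because the admission series here is synthetic (seeded inside the
published ranges), the calibrated \(k\) and duration vary with the seed
and are not the published headline values — those would require the
unpublished monthly admission series. What is stable across any
admission series inside the published ranges is the qualitative
conclusion the sensitivity suite asserts: the calibrated episode
durations stay well below the conventional 7.5 months, i.e. the
conventional \(k = 1.6\) under-estimates the caseload in this setting.

## Known limitations

* First-order Markov ("memoryless"): relapse risk after recovery is not
  elevated; higher-order formulations are out of scope.
* Only admission probabilities vary over time; mortality, recovery and
  outcome probabilities are stationary.
* One prevalence target per tier means no uncertainty interval on
  \(k\); the one-way sensitivity analysis is the uncertainty statement.
* Expected-count dynamics ignore demographic stochasticity — a
  reasonable approximation at governorate population scale, not for
  small camps.
* No age structure, births, or migration; the cohort is closed.
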