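# wastingMarkov

A discrete-time Markov cohort model of child wasting (acute
malnutrition) progression and treatment, for estimating
**context-specific incidence correction factors** and annual treatment
caseloads from routinely collected data.

## The problem

Humanitarian nutrition programs size next year's treatment capacity
(TSFP for moderate wasting, OTP for uncomplicated severe wasting, TFC
for complicated severe wasting) from an annual caseload estimate built
on the relationship

```
Incidence = prevalence × 12 / duration  =  prevalence × k
Caseload  = prevalence × (1 + k)
```

where prevalence comes from an annual cross-sectional SMART survey and
the mean episode duration is conventionally fixed at 7.5 months
(k = 1.6), a value from 1980s cohort studies. Duration — and hence k —
actually depends on local recovery, treatment and mortality rates, and
everywhere it has been re-measured it was far shorter than 7.5 months,
meaning caseloads were under-planned.

`wastingMarkov` estimates k for a specific setting without a cohort
study. It simulates expected counts of children through eight states —
Healthy, ModeratelyWasted, SeverelyWasted, SeverelyWastedComplicated,
the three treatment states, and an absorbing Deceased state — at
monthly transition probabilities taken from program records, surveys
and the literature. The two unknowns, the monthly incidence
probabilities Healthy→ModeratelyWasted and
ModeratelyWasted→SeverelyWasted, are back-calculated by bisection so
that the simulated survey-comparable prevalence (untreated pool plus
the past month's treatment admissions) matches the follow-up survey.
The calibrated probabilities yield annual incident cases, k = incident
cases / baseline prevalence, duration = 12/k, and the corrected
caseload. A one-way deterministic sensitivity analysis (50–150% of each
rate) and a seeded synthetic program-data generator complete the
pipeline. The package ships the configuration for the Lahj governorate,
Yemen (August 2018 → October 2019).

## Worked example

The real monthly admission series behind the Lahj analysis is not
public, so `lahj_calibration_inputs()` pairs the packaged census, rates
and survey targets with a seeded synthetic admission series drawn
inside the published per-program monthly ranges:

```r
library(wastingMarkov)

lahj <- lahj_calibration_inputs(seed = 1)
fit <- sequential_calibration(lahj$inputs, lahj$targets$severe,
                              lahj$targets$moderate)
fit$severe
#> <calibration_result> tier severe
#>   incidence probability : 0.073988 /month
#>   annual incident cases : 18080.6
#>   baseline prevalence   : 4199
#>   k                     : 4.31
#>   episode duration      : 2.79 months
#>   achieved vs target    : 3733.000 vs 3733.000 (month 14, 24 iterations)

caseload_report("severe", 4199, k_context = fit$severe$k)
#> <caseload_report> tier severe (baseline prevalence 4199)
#>   k 1.60 -> caseload 10917 (conventional)
#>   k 4.31 -> caseload 22280 (context-specific)
#>   increase: 104.1%
```

Reading this: with these admission series, a severe wasting episode in
Lahj lasts on average 2.79 months, not 7.5; 4.31 annual incident cases
arise per prevalent case instead of the conventional 1.6; and the OTP
caseload implied by the August 2018 prevalence of 4,199 severe cases is
roughly double the conventional estimate. The exact k varies with the
(seeded) admission series, but the sensitivity suite asserts the part
that does not: across 50–150% sweeps of the recovery rates, calibrated
durations never come close to 7.5 months.

The synthetic pipeline is fully seeded end to end:

```r
bundle <- generate_scenario(scenario_config(seed = 7))  # records + surveys
cal <- calibrate_scenario(bundle)                       # recovers the truth
c(truth = bundle$truth$p_ms, recovered = cal$severe$probability)
#>      truth  recovered
#> 0.06000000 0.06000859
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "wastingmarkov.R", package = "wastingMarkov")`, with
subcommands `simulate`, `calibrate`, `caseload`, `sensitivity` and
`synthesize`.

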