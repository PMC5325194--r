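# oxytitrate

Oxygen is a scarce, life-saving commodity in the low-resource settings where
most childhood pneumonia deaths occur. A child on oxygen therapy is started
at a flow rate chosen to keep SpO₂ above target, but as the child recovers
the required flow falls — so a flow that is never re-adjusted (titrated)
wastes oxygen. `oxytitrate` is a Monte Carlo model of that waste: it samples
synthetic cohorts of hypoxemic-pneumonia patients, computes the oxygen volume
each patient uses under different titration schedules, and quantifies how
much a facility saves by titrating daily, or near-continuously with an
automated pulse-oximetry system, relative to never titrating after the start
of therapy.

## The model

Each patient *i* is a draw of three independent quantities:

- starting flow **V₀** ∈ {0.5, 1.0, 2.0} L/min, uniform (WHO starting rates
  for infants and children);
- treatment duration **D** ∈ {1,…,5} days with P(D) = {0.32, 0.27, 0.18,
  0.12, 0.11} (from clinical duration-of-therapy data);
- a weaning **profile** A or B, equiprobable, describing the flow the
  patient actually needs over time with weaning rate k = 0.125 L/min/day:

  - profile A: v(t) = V₀ − kt for 0 ≤ t < 3 days, then V₀ − 3k;
  - profile B: v(t) = V₀ for t < 1, V₀ − k(t−1) for 1 ≤ t < 3, then V₀ − 2k.

A titration policy with interval Δt delivers a **zero-order hold** on that
profile: at t = 0, Δt, 2Δt, … the delivered flow is re-set to v(t) and held,
so patient *i* uses

O₂,ᵢ(Δt) = Σ over steps of v(step start) × step length (minutes), in liters,

with the last step truncated at D. Δt = D (never re-titrate) gives exactly
V₀·D·1440 L; Δt → 0 gives the exact integral of the profile. A cohort of
N = 100 patients is evaluated under all scenarios on the *same* draws
(common random numbers), savings = 1 − total(Δt)/total(no titration), and
results are summarised as mean ± SEM over R = 3 replicates. An exact
enumeration oracle over the 30-point parameter support supplies closed-form
expectations and variances for every policy, against which the simulation is
validated.

## Worked example

```r
library(oxytitrate)
study <- run_replicates(n = 100, r = 3, base_seed = 1)
summary(study)
#> Paired titration simulation: N = 100 patients, R = 3 replicates
#> Replicate seeds: 1, 2, 3
#>   Scenario I   total    380 +/- 15 kL  (reference)
#>   Scenario II  total    350 +/- 16 kL;  savings 8.0% +/- 0.6% (30 kL saved, 508 h at 1 L/min)
#>   Scenario III total    336 +/- 16 kL;  savings 11.7% +/- 0.7% (44 kL saved, 737 h at 1 L/min)
```

Scenario I holds the starting rate for the whole treatment, II titrates once
daily, III every 3 minutes. For these 100-patient cohorts, daily titration
saves ~30 kL of oxygen (about 8%) and near-continuous titration ~44 kL
(about 11.7%) — at a standard 1 L/min flow, roughly 500 and 730 extra hours
of therapy. The exact expectations behind these stochastic results:

```r
expected_patient_consumption(policy = titration_policy())$expected_volume
#> [1] 4082.4          # liters per patient with no titration
expected_patient_consumption(policy = titration_policy(1440))$expected_savings
#> [1] 0.07958554      # daily titration
expected_patient_consumption(policy = titration_policy(0))$expected_savings
#> [1] 0.1146384       # continuous limit
```

`cmd_simulate()` / `cmd_expect()` write CSV/JSON reports; a command-line
wrapper lives at `inst/cli/oxytitrate.R`. Cohort distributions can be
overridden from a small YAML/JSON file (`read_cohort_config()`).

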