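# physupply

A Markov state-transition model of the UK consultant-physician pipeline:
from medical-school entry through foundation years (FY), internal
medicine training (IMT) and specialty training (ST) to consultant
working, retirement and exit. The package is for health-workforce
analysts who need to project whole-time-equivalent (WTE) consultant
supply over a multi-decade horizon, compare it against compounding
demand, and quantify policy levers (medical-school places, training
retention, overseas recruitment, less-than-full-time working).

The restricted registries that parameterise the published UK model
(UKMED, the NHS Electronic Staff Record, RCP census data) are not
publicly available, so the package ships a synthetic-data generator
with known ground truth — both for estimator validation and as an
illustrative default configuration at the published 2023 magnitudes.

## The model

States are mutually exclusive combinations of training stage × sex ×
work pattern × dwell index:

* stages `MS1–MS6` (medical school, `MS6` the intercalated year),
  `FY1–FY2`, `IMT1–IMT3`, `ST3–ST7`, temporary-break states
  (`BREAK_POST_FY/IMT/ST/CCT`), `CONS` (consultant), `CONS_RR`
  (retired-and-returned, exactly two years), and an absorbing `EXIT`;
* sex stratification from FY1, less-than-full-time (LTFT)
  stratification from ST3;
* break states carry a dwell clock (maximum two years; a third absent
  year is an exit), the post-CCT break lasts exactly one year.

Each annual cycle the population vector **x**ₜ is redistributed by a
row-stochastic matrix **P** (optionally year-specific), mass arriving in
`EXIT` is harvested to an outflow ledger, and external inflows **b**ₜ
(domestic intake, overseas, portfolio route, re-entry) are added:

    xₜ₊₁ = xₜ P  +  bₜ₊₁,      supply_WTE(t) = Σ_FT cons + 0.65 Σ_LTFT cons

Transition probabilities are estimated from longitudinal person-year
records by destination counting: the number making each transition
divided by the number in the origin state, with departures from
training classified by a three-year look-ahead (back in training within
3 years → temporary break; otherwise → exit). Demand compounds
geometrically from a 2023 base of 20,935 WTE at 1.8 % (medium) or
2.4 % (high) per year; shortfall is demand minus supply.

## Worked example

```r
library(physupply)

cfg  <- default_configuration()          # illustrative 2023-magnitude inputs
proj <- project(cfg$initial, cfg$model, cfg$inflows,
                start_year = 2023, horizon = 25)
proj
#> <projection_result> 2023 - 2048
#>   year headcount      wte
#> 1 2023  22000.00 19613.70
#> 2 2024  22736.80 20216.90
#> 3 2025  23352.59 20714.19
#>   ...
#>    year headcount      wte
#> 24 2046  29702.87 25778.33
#> 25 2047  29881.54 25923.51
#> 26 2048  30051.79 26061.95

tail(shortfall(proj, demand_series(cfg$demand_high, 25)), 3)
#>    year shortfall scenario
#> 24 2046  10343.69     high
#> 25 2047  11065.43     high
#> 26 2048  11814.73     high

trace_cohort(10000, cfg$model, max_years = 60)
#> <cohort_trace> entry MS1|-|-|1 size 10000
#>   mean time to consultant 15.40 y (SD 1.64), 4.4% reach

agreement_percent(21302, 22183)$percent
#> [1] 96
```

Reading the output: under the illustrative baseline, consultant
headcount grows from 22,000 to ~30,100 (19,600 → 26,100 WTE) by 2048,
leaving a ~11,800 WTE gap against high-growth demand. Of 10,000
medical-school entrants, the 4.4 % who follow the physician-specialty
path become consultants after a mean of 15.4 years. Policy scenarios
are applied with `apply_scenario()` / `builtin_scenarios()`
(`intake_ramp`, `exit_reduction`, `combined`, `overseas_half`,
`ltft_drift`).

A thin command-line front end is installed at
`system.file("cli", "physupply", package = "physupply")` with
subcommands `generate`, `estimate`, `project`, `scenario`, `cohort`,
`validate` and `demand`.

## Package layout

* `R/state_space.R` — state enumeration, allowed-transition mask,
  model validation
* `R/estimation.R` — transition estimation, break/exit classification,
  CCT split, consultant-exit decomposition, calibration
* `R/engine.R` — deterministic projection, WTE aggregation, cohort
  tracing, microsimulation, backcast agreement
* `R/demand.R`, `R/scenarios.R` — demand series, shortfall, policy
  modifiers and composition
* `R/synthetic_data.R` — record generator, default configuration,
  recovery fixture
* `R/io_cli.R` — YAML config, pipeline, CSV outputs, CLI dispatcher
* `vignettes/consultant-workforce-model.Rmd` — methods and design notes
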