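---
title: "A Markov state-transition model of the consultant-physician pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov state-transition model of the consultant-physician pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physupply)
```

## The model and its assumptions

`physupply` is a discrete-time Markov cohort model of the UK physician
training pipeline. The population is a continuous-valued vector over
mutually exclusive states; each annual cycle redistributes it by a
row-stochastic transition matrix, harvests the mass arriving in the
absorbing `EXIT` state into an outflow ledger, and then adds the year's
external inflows. Order matters and is a deliberate choice: *transition
first, then inflow*, so new entrants make their first transition the
following year, matching the annual census-style snapshots from which
transition probabilities are estimated. Populations are never rounded;
fractional people are a feature of cohort models, and rounding happens
only in reporting.

The Markov assumption is that next year's state depends only on this
year's state. Where reality has memory, the state space carries it
explicitly:

* **Sex** is a stratum from FY1 onward (progression through medical
  school already absorbs sex differences; thereafter men and women have
  separate rows).
* **Work pattern** (full-time vs less-than-full-time, LTFT) is a
  stratum from ST3 onward and for consultant-role states. LTFT rows of
  the default configuration progress more slowly (a larger same-stage
  dwell probability), which is how calendar time to completion
  stretches without per-person clocks.
* **Temporary breaks** are explicit states with a dwell index. A break
  may last one or two years; a third absent year is, by definition, an
  exit. The post-CCT break (between completing training and taking up a
  consultant post) lasts exactly one year and moves to `CONS` with
  probability 1.
* **Retire-and-return** consultants occupy a two-year `CONS_RR` chain:
  all mass entering it is in `EXIT` exactly two cycles later. Returned
  consultants still deliver service, so `CONS_RR` counts toward supply
  headcount and WTE.

Two structural choices deserve a note. First, consultant entry happens
from ST7 only (directly, or via the one-year post-CCT break): training
is 4 or 5 specialty-training years depending on whether entry was at
ST3 (after IMT2) or ST4 (after IMT3), and both routes end at ST7.
Two-level forward skips exist from ST3, ST4 and ST5 only. Second,
same-stage self-loops are allowed at medical school (repeat years), at
ST levels (the LTFT dwell mechanism above) and at `CONS` (staying in
post); they are disallowed elsewhere, where the diagram's forward
arrows and dwell chains carry all legitimate mass.

Because a single `BREAK_POST_ST` state cannot remember which ST level
preceded the break, its allowed returns are the successors of every
possible pre-break level (ST4–ST7); estimated or configured
probabilities decide the split. Break states below ST level carry no
work-pattern stratum — the pattern is re-chosen on return — while the
post-CCT break does, since its occupants have completed training.

## Estimation from person-year records

`estimate_transitions()` implements destination counting: for each
origin state observed in a cohort year, the empirical distribution of
states one year later, divided by the origin count. The subtleties are
all about absence:

* A person present at year *y* and absent at *y + 1* is **on a
  temporary break** if they reappear in any model stage during
  *y + 2 … y + 3*, and **has exited** otherwise (`classify_departure()`).
  A return at *y + 2* is a one-year break (dwell 1); at *y + 3*, a
  two-year break. The classification needs three years of follow-up, so
  cohort years without it are rejected rather than guessed
  (`physupply_followup_truncated`), mirroring the restriction of the
  source analysis to cohorts with full follow-up.
* Absence runs are reconstructed into break-state dwell chains, so the
  break rows of the matrix are estimated from the same records as
  everything else. An absence between ST7 and `CONS` is the post-CCT
  break.
* Origins never observed get denominator 0 and are *flagged*, then
  filled by the pooled-sex estimate for the same stage/pattern/dwell
  when available, else by a deterministic forward fallback — a small
  synthetic sample must yield a projectable model, but the flags keep
  the substitution visible.

`split_cct()` combines a completion probability with the three-way
post-CCT destination split (direct consultant / one-year break / leave),
`consultant_exit_decomposition()` splits total consultant exit into
retire-and-return and direct exit, and `calibrate()` rescales a
destination group of selected rows to a target marginal, renormalizing
the rest of each row by a common factor (idempotent by construction).
Calibration is applied to the starting matrix only; time variation
enters through scenario overrides, so every applied yearly matrix is
validated.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `ltft_weight` | 0.65 | WTE per LTFT consultant | published average participation of LTFT consultants |
| demand base | 20,935 | WTE in 2023 | consultant establishment grossed up for the 2023 vacancy rate; taken as a direct input because the published derivation of the 5.4 % uplift is not fully specified (`demand_from_supply()` offers both conventions) |
| demand growth | 0.018 / 0.024 | per year | published medium / high demand-growth forecasts, extrapolated unchanged to the horizon |
| intake ramp | 10,000 → 17,000 by 2031 | places/year | national expansion plan, linear by assumption |
| exit reduction | post-IMT exit mass → 0.10; post-FY → 0.70 | probability | the two published 16 % post-IMT components each fall to 5 %; the 15 % post-FY leaving component falls to 5 % inside that row's larger exit mass (which also contains movement to non-physician specialties) |
| LTFT drift | +1 pp/yr (ST), +5 pp/yr (consultant entry), cap 0.70 | share/year | *additive* percentage points: over 25 years this reproduces the published end-point stock shares (ST roughly 25 % → 50–60 %, consultants 31 % → 50 %), which a 1 %-relative reading cannot; `relative = TRUE` switches readings |
| `max_break_dwell` | 2 | years | a third absent year is an exit by definition |
| microsim agents | 10⁵ | agents | binomial noise ≈ 0.3 % of a typical state, small enough to resolve modelling errors |

The drift modifier changes only the FT/LTFT split of progression and
consultant-entry destination pairs; the total progression mass of every
row is untouched, so headcount dynamics are preserved while WTE falls.
Rows whose base LTFT share already exceeds the cap (e.g. progression
*within* the LTFT stratum, where staying LTFT is the norm) are held at
base with a warning rather than forced down.

## What the synthetic generator does and does not emulate

`generate_records()` draws each person's annual state sequence from a
known ground-truth matrix, then *degrades* it exactly the way the real
registry data are degraded: break years become `ABSENT` rows, exits
become permanent absence, and the work-pattern flag only exists where
the observed stage carries one. Ground-truth break semantics are
defined to be the model's break states, so estimator recovery isolates
estimator correctness from model misspecification. The generator keeps
its own departure labels (break vs exit, decided by the realized
return) so the three-year rule can be checked against truth exactly.

It does **not** emulate: real identifier systems or linkage error,
COVID-era disruption, measurement error in the LTFT flag,
cohort-to-cohort drift in true probabilities, or re-entry after
long (> 2-year) gaps as anything other than fresh inflow. Passing
recovery tests therefore show the estimator is correct *given the
model's absence semantics*, not that the model captures every real
process.

The **default configuration** is anchored where magnitudes are public —
consultant headcount ≈ 22,000 and WTE ≈ 20,000 in 2023 (31 % LTFT at
0.65 WTE gives the 0.8915 WTE/headcount ratio), ST LTFT ≈ 25 %,
medical-school intake ≈ 10,000/year, post-IMT exit 32–33 % — and
plausible but explicitly illustrative elsewhere (foundation-year
stocks, overseas and portfolio inflow volumes, retire-and-return
rates). It is *not* the calibrated input set of the published model,
which derives from restricted data; headline outputs (e.g. the ~11,800
WTE 2048 shortfall against high demand, the 15.4-year mean time to
consultant) are therefore data-dependent illustrations, not
reproductions.

The **recovery fixture** (`recovery_generator_spec()`) is designed by a
binomial power calculation: with 50,000 persons (70 % entering MS1,
30 % directly into the ST3 LTFT strata) observed for 20 years,
mid-range probabilities appear only on rows whose person-year
denominators make a ±0.01 recovery bound comfortable at ~3–4 standard
errors, while thinly occupied rows (break dwell chains, post-CCT,
retire-and-return) are degenerate and estimate exactly. Post-FY breaks
in the fixture always dwell two years so the two-year absence machinery
is exercised deterministically.

## Numerical choices

* Row-stochasticity tolerance is 1e-12; conservation of mass is checked
  to 1e-9 relative and holds to machine epsilon in practice, because
  the engine never renormalizes — any leak would surface.
* `project()` and `microsim()` refuse matrices with negative entries or
  bad row sums, but only *warn* about mass on disallowed pairs: such a
  matrix is a modelling defect yet propagates perfectly well, and
  reference dynamics (an identity matrix, hand-built chains) are useful
  in testing. `validate_transition_model()` reports all three defect
  classes; scenario machinery requires a fully clean model.
* The microsimulation draws multinomial destination counts per occupied
  origin — agent-level dynamics without per-agent bookkeeping. Initial
  mass is allocated to agents by largest remainder; fractional inflow
  agents are rounded stochastically (unbiased). Its agreement bound
  uses the conservative variance `N p (1 − p)` with `p` the
  deterministic share of all mass ever in the system.
* `trace_cohort()` makes consultant entry absorbing and accumulates
  first-passage mass; with geometric-dwell chains its mean matches the
  closed form Σ 1/p to 1e-9 when `max_years` is generous (truncation
  bias decays geometrically; 250 years suffices for the test chains).
* Ties and degenerate inputs: an empty cohort set flags every origin;
  a zero cohort yields an empty trace; `compose_scenarios()` rejects
  two exit overrides that set the same cell group to different values.

## Problem sizes

The shipped tests run the full 65-state space: 25-year projections,
a 100,000-agent microsimulation, and estimator recovery at 50,000
persons (≈ 8 × 10⁵ person-year rows, ≈ 120 checked probabilities);
smaller property tests use 2,000–20,000 persons. These sizes were
chosen so binomial noise sits well inside the stated tolerances while
a complete run stays interactive on a single core.

## Known limitations

* Inputs are assumed time-constant unless a scenario varies them; real
  exit and retirement rates drift with workforce demographics.
* The model pools physician specialties; no specialty-level structure,
  no locum state, no cost side.
* Demand is a geometric extrapolation of published growth rates; no
  uncertainty bands. Probabilistic sensitivity analysis is the natural
  next step and is deliberately out of scope.
* The estimator is a frequency counter: no interval censoring,
  smoothing or survival machinery. With registry-scale denominators
  that is the published method; with small samples the flags and
  fallbacks matter and should be inspected.
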