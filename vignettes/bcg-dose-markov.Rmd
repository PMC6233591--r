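---
title: "Methods: a Markov cohort model of BCG dosing in NMIBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of BCG dosing in NMIBC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgdose)
```

## The decision problem

Intravesical Bacillus Calmette-Guérin (BCG) after transurethral resection
(TUR) is standard adjuvant therapy for intermediate- and high-risk
non-muscle-invasive bladder cancer, but the optimal dose is contested:
reduced doses lower cost and toxicity, possibly at the price of more
recurrences. `bcgdose` models a cohort of such patients under a full dose
(81 mg) and a low dose (27 mg), both with one year of maintenance, and
compares expected overall survival over a 20-year horizon — chosen to
cover the realistic remaining life expectancy of a cohort with mean age
in the mid-60s.

## Model structure and assumptions

Five health states with annual cycles: *tumor free after TUR*, *no
recurrence*, *tumor free after RC* (radical cystectomy), *metastasis*,
and absorbing *death*. The structural assumptions, each of which shapes
the transition matrix built by `build_matrix()`:

* **Recurrence without worsening** is managed by repeat TUR plus BCG and
  returns the patient to the tumor-free-after-TUR state (the state's
  self-loop represents exactly this: recurrence, resection, re-induction).
* **Recurrence with worsening** mandates RC. Perioperative mortality is
  embedded in the transition: with worsening probability $p_w$ and
  surgical mortality $m$, the flow splits into $p_w(1-m)$ to the post-RC
  state and $p_w m$ to death. Competing risks within a cycle are a single
  multinomial draw per row — the standard one-cycle decision-tree
  embedding; the published exit masses stay well below 1, so no
  normalisation is needed.
* **The no-recurrence state retains the full annual recurrence risk**
  (identical exit row to the post-TUR state, differing only in the
  staying destination). The source flow diagram is ambiguous on this
  point, but this reading is the only one consistent with the published
  repeat-TUR volumes (≈ 2602 / 3960 operations per 10,000 patients over
  20 years, which require the recurrence hazard to persist over the
  cohort's ~9.5 expected life-years). We treat it as the leading
  structural assumption; the acceptance tolerances, rather than
  bit-exactness, absorb the residual uncertainty.
* **Age-specific mortality applies to disease-free states only** (post-
  TUR, no recurrence, post-RC). The metastatic state carries only its own
  death probability — adding background mortality there would double-count
  death risk in the state where it is already highest.
* **RC is irreversible**; metastasis is reachable only after RC; death is
  absorbing. These structural zeros are asserted by tests and respected
  by every simulated trajectory.

A consequence worth knowing: because the two bladder-intact disease-free
states share the same exit probabilities, shuffling patients between them
(the role of recurrence *without* worsening) does not change survival.
Expected life-years depend on each arm's *worsening* probability only,
which is why the one-way crossover on either arm's worsening probability
falls exactly at the other arm's base value — ≈ 0.0270 and 0.0370 here,
matching the published 0.0271/0.0371 to their printed precision — and why
recurrence without worsening is a cost (repeat surgery) rather than a
survival driver.

## Parameters

All parameters are annual probabilities stored as fractions; displays
show percent alongside. `default_parameters()` holds the base case,
`default_ranges()` the sensitivity ranges:

```{r}
tidy(default_parameters())
default_ranges()
```

Age-specific mortality (0.0791) is a single constant: the source fixes
one value for the whole horizon despite the "age-specific" name.
`run_cohort()` accepts an optional per-cycle mortality vector for users
who want an actual age schedule; the constant is the default and the
tested configuration. Age-specific mortality also has no published
sensitivity range; where one is needed (tornado diagrams) we apply a
±20 % relative band, exposed as `rangeless_band` and documented as an
analysis convention — only the qualitative ranking of its bar is treated
as meaningful.

The DEALE helpers (`rate_from_median()`, `rate_from_cumulative()`,
`rate_to_annual_prob()`, `prob_to_rate()`) document how annual
probabilities of this kind are derived from survival figures under a
constant-hazard approximation. The base-case table already reports annual
probabilities, so the engine consumes them directly; the helpers exist
for provenance and for re-deriving inputs from other studies.

## Outcomes and numerical choices

* **Life expectancy** uses the trapezoidal half-cycle correction on the
  alive fraction, $\sum_{t=1}^{T} \tfrac12 (a_{t-1} + a_t)$ — the textbook
  form of the correction the model class cites. Under pure age mortality
  this reduces to a closed geometric form, which the tests match to
  1e-10.
* **Operation counts** tally operations performed, not survivors: the
  repeat-TUR count is the recurrence-without-worsening flow out of both
  bladder-intact disease-free states; the RC count is the full worsening
  flow *including* patients dying at surgery.
* **Crossover localisation** brackets a sign change of the LD−FD
  life-year difference on the sweep grid and bisects to 1e-5 in the
  parameter value. The difference is a smooth deterministic function of
  any one parameter, so bisection on the cohort model (never on
  simulation output) is exact for practical purposes. A difference that
  is identically zero across the range (tied arms) is reported as *no
  crossover*.
* **Two-way grids** label each cell by the arm with the higher expected
  life-years; exact floating-point equality — which arises structurally
  when the arms' parameters coincide — is labelled a tie.
* **Microsimulation** draws one uniform per patient-cycle from a
  pre-allocated matrix. Running both arms with the same seed therefore
  uses common random numbers, the standard variance-reduction device for
  paired strategy comparison: the paired LD−FD difference at $n$ =
  10,000 reproduces the deterministic +0.06 y ordering reliably, while
  two independent runs of that size would not. Death during cycle $t$
  contributes $t - \tfrac12$ life-years, matching the cohort engine's
  half-cycle convention; the median of these discrete times is reported
  with linear interpolation inside the death cycle.
* **Second-order uncertainty** is offered explicitly as `psa()`: uniform
  sampling over each parameter's published range (no distributional
  information beyond the ranges is available), deterministic cohort
  evaluation per draw by default. The 10,000-patient "Monte Carlo" run
  of the source analysis is, by its reported CI width, first-order
  patient-level sampling at fixed parameters; we implement that as
  `simulate_patients()` and keep the two notions separate in the
  documentation.

## The synthetic-data generator

`generate_panel()` draws i.i.d. patient trajectories from the model's own
transition matrix — it emulates the statistical structure the transition
probabilities assume (annual multinomial moves, constant hazards,
no censoring), standing in for the trial data behind the parameter
table. `estimate_params()` recovers each probability as events over
person-cycles at risk with exact binomial confidence intervals.

The worsening split is only identifiable because the generator marks
deaths at surgery (`rc_death`) separately from other deaths — real
registry data may not; `surgery_marker = FALSE` suppresses the marker,
upon which the package honestly reports the recurrence-with-worsening
probability and RC mortality as non-identifiable and returns the
identifiable combination $p_w(1-m)$ instead, with age mortality estimated
from the post-RC state alone.

What passing recovery tests show is internal consistency — generator,
engine and estimator agree — not external validity: the generator has no
censoring, no covariates, no time-varying hazards, no risk-group
stratification, and its constant annual probabilities are exactly the
model's assumption, not a property of real NMIBC cohorts.

## Problem sizes used by the test suite

The deterministic analyses are desk-scale (a 5×5 matrix over 20 cycles).
The stochastic checks use sizes chosen to make their tolerances sharp but
cheap: 50,000 patients for law-of-large-numbers agreement with the cohort
trace (3 standard errors), 10,000 patients — the source analysis's size —
for the paired-arm microsimulation check, and 100 seeded replications of
5,000-patient panels for parameter-recovery coverage (exact binomial CIs
make coverage independent of the panel size, so the smaller panels trade
nothing but variance in the coverage estimate itself).

## Known limitations

* No costs, utilities or QALY weighting — the comparison is survival
  only, with surgery counts as a cost proxy.
* No toxicity or side-effect states, although dose-dependent toxicity is
  one clinical motivation for the low dose; to the extent toxicity
  shortens survival, its effect is implicit in the arms' published
  transition probabilities.
* Constant hazards throughout; no tunnel states, no time-on-treatment
  effects beyond the one-year maintenance embedded in the source
  probabilities. The 3-year-maintenance variant can be explored via
  custom parameter configs but has no packaged defaults.
* No risk-group stratification: the cohort pools intermediate- and
  high-risk patients exactly as the source probabilities do.
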