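---
title: "Methods: planting and harvest scheduling under GDU uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planting and harvest scheduling under GDU uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gduplan)
```

## The scheduling problem

A seed production site plants N corn seed populations, each described by a
planting window `[l_i, u_i]` (week indices), a heat requirement `G_i^min`
(growing degree units, °C-based), and a harvest quantity `HQ_i` (ears).
The modelling assumptions, inherited from the production setting:

* **Weekly resolution.** Crop growth is tracked per calendar week; week 1
  starts January 1 and later weeks start on Sundays (the spreadsheet
  WEEKNUM convention), continuing past December into the next year so a
  70-week horizon is a single index range.
* **Earliest harvest.** A population planted in week `p` is harvested in
  the first week `h` whose post-planting cumulative GDU reaches `G_i^min`:
  `cum(h) − cum(p) ≥ G_min > cum(h−1) − cum(p)`. Heat counts from the week
  *after* planting through the harvest week inclusive. Consequently the
  planting schedule is the only real decision; harvest dates follow from
  whichever weekly GDU series materializes.
* **Hard windows, hard maturity.** Planting outside `[l_i, u_i]` is not
  allowed, and a population that cannot reach `G_i^min` from any window
  week within the horizon makes the instance infeasible — solvers report
  the offending populations rather than dropping them. A site whose heat
  supply is too low therefore fails loudly, which is the correct diagnosis
  for a cold site rather than an artifact.

Two capacity regimes are modelled. With a fixed storage capacity `C`
(case 1) the goal is weekly harvest quantities close to `C` on every
harvesting week, so the objective is `Σ_j |w_j C − A_j|` with `w_j`
indicating harvest weeks and `A_j` the weekly quantity. Without a
predefined capacity (case 2) the goal is the lowest capacity a schedule
can get away with: `min max_j A_j + θ_w · #harvest-weeks`, where `θ_w`
(default 1 ear-equivalent per week) discourages smearing the harvest over
many weeks.

## Linearizations

Both nonlinear objectives are reformulated exactly:

* absolute values via `w_j C − A_j = e_j^+ − e_j^-`, `e^± ≥ 0`, minimizing
  `Σ (e^+ + e^-)`. At any optimum `min(e_j^+, e_j^-) = 0` week by week, so
  `e_j^-` equals the over-capacity excess; the test suite checks (rather
  than imposes) that it vanishes whenever every active week fits under
  `C`.
* the minimax via a continuous peak variable `z ≥ A_j` for all weeks, with
  objective `z + θ_w Σ w_j`.
* the earliest-harvest rule via the constraint pair on cumulative GDU
  (reach at the harvest week; not-yet-reached at the week before). The
  published integer-GDU form subtracts 1; since real GDU series are
  continuous the strict inequality is realized as
  `≤ G_min − ε` with `ε = max(10⁻⁶ · G_min, 10⁻⁴)` heat units. A week
  whose shortfall is inside `(G_min − ε, G_min)` would be mis-classified;
  with continuous synthetic series this event has probability zero, and
  the engine-side evaluator always uses the exact strict inequality.

The multi-scenario (stochastic) case 1 model shares one set of planting
binaries across K scenarios, gives each scenario its own harvest binaries
and earliest-harvest pair, and prices the weekly **max envelope**
`A_j^max = max_k A_jk`. Lower bounds `A_j^max ≥ A_jk` alone would let the
solver inflate the envelope toward `C` and claim zero deviation, so the
envelope is pinned exactly with per-week scenario-selection binaries
`y_jk` (`Σ_k y_jk = 1`, big-M upper bound with `M = Σ HQ_i`, attained
because the selected scenario must be an argmax). The scenario-equality
constraint published for the stochastic model (accumulated GDU exactly
equal to `G_min` per scenario) is unsatisfiable for continuous heat units;
following the accompanying prose ("harvested as soon as they accumulate"),
the package uses the earliest-reach inequality pair per scenario.

**Objective convention.** Summing `|C − A_j^max|` literally over all T
weeks charges `C` for every idle week, rewarding schedules that smear
harvest across the whole horizon — the opposite of the stated goal of few,
consistent harvest weeks. The default therefore sums over *active* weeks
only (some scenario harvests something); `all_weeks = TRUE` reproduces the
literal reading, in both the evaluators and the MILP.

The dense form of this model has `N·K·T + N·T + K·T + T` decision
variables (per-scenario harvest binaries, planting binaries, per-scenario
weekly indicators, envelope). `stochastic_variable_census()` reproduces
that count by enumerating the index sets, and an `audit_dense` build is
census-identical; the production build sparsifies planting binaries to
windows and harvest binaries to reachable weeks, which preserves the
optimum. The deviation auxiliaries `d^±` and the active-week indicators
belong to the absolute-value reformulation and are deliberately outside
the census.

## Simulated annealing

The exact stochastic model is out of reach at production scale (about a
million binaries for a thousand populations), so the package includes the
simulated annealing heuristic with the problem-specific neighborhood:

1. find the active week with the largest envelope value; among the
   populations harvested there (under the scenario attaining that value),
   shift the `moves_per_max_week = 3` with the smallest `HQ_i` by ±1 or ±2
   weeks, uniformly over shifts that stay inside the window and keep the
   population maturable under every scenario (a population with no
   feasible shift is skipped and logged);
2. find the active week with the smallest envelope value; from the closest
   week with a strictly larger value (ties toward earlier weeks, then
   smaller ids), re-plant one population so its harvest lands on the
   shallow week under the scenario attaining that week's value, when such
   a planting week exists.

Cooling is geometric, `T_0 α^k` with defaults `T_0 = 30000`, `α = 0.995`,
`k_max = 700`. Acceptance is standard Metropolis
(`exp(−(E_new − E_cur)/T)` for worsening moves): the published acceptance
exponent has its sign flipped and would accept every worsening move; that
literal variant is kept behind `acceptance = "literal"` for comparison
only. The min/max weeks are recomputed from the *current* (not best)
schedule each iteration, and one population is re-planted per iteration in
step 2 — both points the source description leaves open. Energies of
returned schedules are always re-derived through the public profile
evaluator; with integer ear counts the identity is exact.

**Known limitation (measured by the test suite).** The neighborhood only
ever moves populations harvested at the current envelope's extreme weeks.
At production scale, where a single population is a small fraction of a
week's harvest, that greedy pressure is effective; on the oracle-enumerable
toys used for testing (N ≤ 6), each population is a sizeable share of its
week and optimal schedules often require re-planting a population harvested
at an *interior* week — a move the neighborhood never proposes. The
acceptance suite measures the exact-hit rate of 2000-iteration runs against
brute-force optima on a frozen toy family and the ≥ 90% quality bar is not
met (the rate is strongly bimodal per instance, the signature of move-graph
reachability rather than sampling noise). The companion guarantees do hold
on every run: schedules are always window- and maturity-feasible, and never
beat the exact optimum.

## Synthetic instances

Real challenge data is NDA-bound, so `generator_config()` states a
synthetic world chosen once:

* planting windows a few weeks wide (start uniform in weeks 2–30, width
  3–10), the shape reported for the real sites;
* required GDU uniform in 1200–1600 °C-units, the agronomic range for
  grain corn relative maturities;
* harvest quantities log-normal (`meanlog = log 150`, `sdlog = 0.6` ears)
  — right-skewed with a long tail — and case 2 quantities a uniform
  1.2–2.0 multiple of case 1, matching the observation that the
  unconstrained-capacity case stores more ears (the published site totals
  imply a ratio near 1.4);
* weekly GDU as a sinusoid peaking midsummer
  (`mean 55 ± amplitude 50` heat-units/week, i.e. winter ≈ 5, summer
  ≈ 105 ≈ 15 GDU/day) plus i.i.d. Gaussian weekly noise (sd 8) and an
  additive site offset; series wrap past week 52 so the 70-week horizon
  re-enters the same synthetic year's spring, preserving each scenario's
  climate identity (the source leaves the extension unstated).

Capacity is either explicit or a stated quantile (default 0.75) of the
positive weekly envelope demand under midpoint-of-window planting.
Feasibility is guaranteed by construction: any population whose requirement
is unreachable from its earliest window week under some scenario has the
requirement redrawn below the reachable maximum, and the repair is logged
(`allow_infeasible = TRUE` disables this to produce cold-site instances on
purpose). What the generator does **not** emulate: spatial/temporal
correlation of weather beyond the seasonal mean, correlation between a
population's window, requirement and quantity, and the real sites'
empirical distributions (unavailable). A green test therefore establishes
correctness of the algorithms on instances with the right marginal shapes,
not predictive performance on the NDA-restricted production data.

## Forecasting stage

The GDU prediction stage is reduced to its load-bearing skeleton: a lagged
same-week supervised dataset (`G_y^w` explained by the same week of the k
prior years), a climatology baseline (mean of the lags; persistence at
k = 1), standard metrics (RMSE, MAE, Pearson r), and a rolling two-year
forecast that predicts the next year week by week and then feeds those
predictions back as lag inputs for the opening weeks of the year after.
Neural sequence models are deliberately not re-specified — any object with
`fit(features, target)` / `predict(state, features)` slots into
`rolling_forecast()` — because their published results are bound to the
NDA data and the pipeline, not the weights, is what the scheduling models
consume.

## Numerical and engineering choices

* **Solver backend.** No MILP solver ships with the target R library set,
  so models are serialized to JSON and solved by HiGHS through SciPy's
  `milp` in a `python` subprocess (batched, one interpreter start per
  batch). The models themselves are built and owned in R; binaries are
  extracted at a 0.5 threshold and every result is re-validated and
  re-priced by the GDU engine, so solver numerics cannot corrupt results.
  Capacity-sizing solves default to the 0.1% optimality-gap stopping rule.
* **Tie-breaks** are fixed for determinism: earliest week, then smallest
  population id, everywhere a tie can occur; the annealer is exactly
  reproducible from `(instance, config, seed)`.
* **Degenerate inputs**: zero-GDU weeks (flat cumulative runs) are handled
  by the strict-inequality search; empty profiles price to 0; a
  single-scenario stochastic model reduces exactly to the deterministic
  one (tested).
* **Scale of the test battery**: oracle checks run on instances small
  enough for exhaustive enumeration (≤ ~5⁶ assignments), which finishes in
  seconds yet exercises every constraint family of the full-size models.
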