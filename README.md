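# gduplan

Optimization toolkit for **corn planting and harvest scheduling** driven by
heat-unit phenology. Seed producers plant hundreds of corn seed populations,
each with its own allowed planting window, its own heat requirement to reach
maturity, and its own expected harvest quantity. Because every population
must be harvested in the first week it accumulates its required growing
degree units (GDU), the planting schedule alone determines the weekly flow
of ears into a storage facility — and a poor schedule produces weeks that
overflow the facility next to weeks that leave it idle. `gduplan` is for
operations researchers and production agronomists who want to optimize that
schedule, and for anyone who needs a reproducible benchmark of the
underlying models.

## The models

Heat accumulates daily as

```
GDU = (clamp(Tmax) + clamp(Tmin)) / 2 − 10 °C
```

with both temperatures clamped into [10 °C, 30 °C], summed into calendar
weeks (week 1 starts January 1; later weeks start on Sundays). A population
planted in week *p* with requirement `G_min` is harvested in the first week
*h* with `cum(h) − cum(p) ≥ G_min`.

Four objectives over the planting binaries `t_p[i,j]` (one week inside each
population's window `[l_i, u_i]`):

* **Case 1, one GDU scenario** (fixed storage capacity *C*):
  minimize `Σ_j |w_j C − A_j|`, the weekly deviation between capacity and
  the harvested quantity `A_j = Σ_i HQ_i · [h_i = j]`, linearized exactly
  with deviation variables `e⁺, e⁻`.
* **Case 2, one scenario** (capacity sizing): minimize
  `max_j A_j + θ_w · #{harvest weeks}`, linearized with a peak variable
  `z ≥ A_j`; the optimal `z` is the lowest storage capacity required.
* **Case 1, K historical scenarios**: one shared planting schedule, one
  harvest date per scenario, minimize `Σ_j |C − A_j^max|` where
  `A_j^max = max_k A_jk` is the weekly max envelope across scenarios —
  an exact MILP with a linearized envelope, plus a simulated annealing
  heuristic (geometric cooling `T0 α^k`, defaults 30 000 / 0.995 / 700
  iterations) whose neighborhood shifts the smallest populations off the
  tallest envelope week and re-plants one population onto the shallowest.
* **Case 2, K scenarios**: the annealer with the envelope total-variation
  energy (sum of absolute differences between consecutive active envelope
  values), reporting the envelope peak as the capacity to size for.

MILPs are described solver-agnostically in R and solved through HiGHS (via
SciPy's `milp`, using the system `python`); every returned schedule is
re-validated and re-priced by the GDU engine, never trusted from the
solver. Real challenge data sits under an NDA, so a synthetic generator
reproduces its statistical shape (windows a few weeks wide, right-skewed
harvest quantities, seasonal weekly GDU curves with year-to-year noise) and
every test runs from code alone.

## Worked example

```r
library(gduplan)

cfg  <- generator_config(n_populations = 15, n_scenarios = 3, seed = 42)
inst <- generate_instance(cfg, capacity_rule = "quantile")
inst
#> <gdu_instance: N=15 populations, K=3 scenario(s), T=70 weeks,
#>  capacity C=229 ears, hq_case=1>

# deterministic case 1 on the first scenario
det <- gdu_instance(inst$populations,
                    list(gdu_scenario(inst$gdu[, 1], "year01")),
                    capacity = inst$capacity)
res <- solve_case1(det, rel_gap = 0.001)
res
#> <gdu_solve_result: status=optimal, objective=693 (solver 693, gap 0)>
sum(res$profile$A_max > 0); max(res$profile$A_max)
#> 9 active weeks, peak weekly harvest 468 ears

# capacity sizing (case 2): lowest capacity plus week penalty
solve_case2(det, rel_gap = 0.001)$capacity
#> 468

# stochastic case 1 across all three scenarios, simulated annealing
sa <- sa_anneal(inst, sa_config(k_max = 700, seed = 1))
sa$result
#> <gdu_solve_result: status=feasible, objective=1442 (solver 1442, gap NA)>
```

The case 1 objective (693) is the summed weekly gap, in ears, between the
229-ear capacity and what arrives each harvesting week; case 2 reports that
no schedule can push the peak week below 468 ears. The annealer's energy
(1442) is the same capacity-gap sum measured on the worst scenario per week
(the max envelope), for one planting schedule shared by all three GDU
years.

A command line mirrors the API
(`inst/cli/gduplan simulate | solve-det | solve-stoch-milp | solve-sa |
forecast | evaluate`).

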