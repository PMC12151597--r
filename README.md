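# weedbeetle

Population-dynamic models for the initial stages of beetle biocontrol of
*Tradescantia fluminensis*, a clonal invasive ground cover. The package is
for ecological modellers and biocontrol practitioners who want to ask:
**how many adult beetles per 100 plant leaves must be released for the
stand to be consumed?** — and how sensitive that number is to every
demographic parameter.

Three beetle species are built in as presets, differing in what their
juveniles destroy:

| preset | species | juveniles graze |
|---|---|---|
| `"leaf"` | *Neolema ogloblini* | leaves |
| `"tip"`  | *Neolema abbreviata* | growing tips |
| `"stem"` | *Lema basicostata* | stem nodes (and their leaves) |

## The models

* **Stochastic plant** — an explicit tree of nodes, leaves and growing
  tips. Per time step `dt = 0.1` d: every node branches with probability
  λ<sub>B</sub>·dt, every tip grows a new leaf-bearing node with
  probability λ<sub>G</sub>·dt, and every live node adjacent to a dead
  node dies with probability λ<sub>D</sub>·dt (death creeps outward from
  the dead basal node).
* **Mean-field plant** — dT/dt = λ<sub>B</sub>N,
  dN/dt = dL/dt = (λ<sub>G</sub> − λ<sub>D</sub>)T, with asymptotic
  growth rate Λ = √(λ<sub>B</sub>(λ<sub>G</sub> − λ<sub>D</sub>)) ≈
  0.0159 d⁻¹ at the default rates.
* **Beetles** — two stages: dJ/dt = −rJ + bA − μ<sub>J</sub>J,
  dA/dt = rJ − μ<sub>A</sub>A.
* **Coupled model** — seven states (T, N, L, LX, TX, J, A) with Holling
  type-II grazing x/(α + x), damaged tips that no longer grow but still
  spread basal death, leaf-limited adult recruitment and starvation
  mortality. Tip growth scales with per-node leaf availability
  (G = λ<sub>G</sub>·L/N), so a beetle-free stand reduces exactly to the
  plant-only model; see the methods vignette
  (`vignettes/biocontrol-model.Rmd`) for that design decision and its
  alternatives.

## Worked example

```r
library(weedbeetle)

plant_growth_rate(plant_params())
#> [1] 0.01588018          # beetle-free leaf growth rate, per day

pr <- species_preset("stem")
beetle_growth_rate(pr$beetle)
#> [1] 0.008299359         # stem-beetle intrinsic rate: slower than the plant

run_release(P0 = 100, B0 = 20, species = "stem")
#> # A tibble: 1 × 5
#>      P0    B0 classification damage time_of_consumption
#>   <dbl> <dbl> <chr>           <dbl>               <dbl>
#> 1   100    20 consumed            1                130.

critical_release_size(100, "stem")
#> [1] 15                  # smallest consuming release for a 100-node stand

critical_release_per_100_leaves("stem")
#> [1] 11.18               # large-stand threshold per 100 leaves
```

A release of 20 stem-beetle adults onto a 100-leaf stand strips every
leaf within 130 days; bisection puts the smallest such release at 15
adults. Because the plant outgrows the beetle (0.0159 vs 0.0083 d⁻¹),
releases below the threshold end in coexistence with both populations
growing. On large stands the threshold is near-linear in stand size, and
`critical_release_per_100_leaves()` reports its slope — about 11 stem
beetles per 100 leaves.

Other entry points: `simulate_plant()` / `simulate_plant_ensemble()`
(stochastic runs), `integrate_model()` (any of the ODE systems),
`lifespan_to_rate()`, `fit_tip_growth_rate()`, `fit_juvenile_mortality()`,
`fit_grazing_rate()` (calibration), `damage_map()`, `sensitivity_mc()` +
`sensitivity_regression()` (with `tidy()`/`glance()` methods), and
`plot_trajectory()` / `plot_damage_map()` / `plot_sensitivity()`.
A thin CLI over the same functions ships in `inst/cli/weedbeetle.R`
(subcommands `simulate-stochastic`, `simulate-ode`, `calibrate`,
`threshold`, `heatmap`, `sensitivity`).

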