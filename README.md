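# frontobstacles

Models of population range expansions through habitats containing compact
**growth-free obstacles** — regions (a lake, a nutrient-poor patch, a lawn of
phage-resistant bacteria) where an advancing population cannot reproduce.
The package is aimed at quantitative ecologists, microbial evolution labs and
physicists of pulled fronts who want to predict (i) how an obstacle distorts
a population front and how the distortion heals, and (ii) how the distortion
reshapes the genetic composition of the expanding population
("geometry-enhanced genetic drift").

Three engines share one geometry layer:

| engine | description | entry points |
|---|---|---|
| constant-speed (eikonal) | front advances at speed `v` normal to itself; obstacles delete overlapping segments | `front_rhombus()`, `indent_rhombus()`, `circle_axis_lag()`, `solve_arrival()`, `marker_path()` |
| reaction-diffusion (FKPP) | `du/dt = D ∇²u + k(x) u (1 − u)` with `k = 0` inside obstacles | `fkpp_params()`, `initial_condition()`, `fkpp_integrate()`, `extract_front()` |
| stochastic Eden | one individual per hexagonal-lattice site, genotype labels, full genealogies | `eden_config()`, `eden_run()`, `genealogy()`, `detect_pinned_boundary()` |

The science in brief. For a rhombus-shaped obstacle of half-width `w` and
half-height `h`, the constant-speed front wraps the obstacle in circular
arcs that meet its edge at 90°, a kink forms on the axis after the front has
traveled `d = sqrt(w² + h²)` beyond the widest point, and the indent then
heals as

```
Δ(d) = d (1 − sqrt(1 − w²/d²))  ≈  w²/(2d)   for d ≫ w
```

independent of `h`: the long-range perturbation is set by the obstacle's
*width*, not its shape (a disk of radius `r` heals with the same law,
`w = r`). The FKPP front lags this prediction by an amount tied to the front
width `ξ = sqrt(D/k)`, vanishing as obstacles grow large compared with `ξ`.
In the stochastic engine, genotypes hitting the obstacle head-on are lost,
genotypes grazing its flanks sweep the shadow, and a sector boundary is
pinned at the obstacle top. See the vignette
(`vignettes/obstacle-fronts.Rmd`) for models, assumptions and numerical
choices.

## Worked example

```r
library(frontobstacles)

# closed forms: kink distance and indent for the wide printed rhombus
kink_distance_rhombus(1.2, 0.9)        # 1.5 (mm)
indent_rhombus(c(2, 4, 8), 1.2)        # 0.40000000 0.18424319 0.09051203

# the front meets the obstacle at a right angle while wrapping it
ob  <- make_rhombus(1.2, 0.9)
contact_angle(front_rhombus(0.75, 1.2, 0.9), ob)   # 89.99999 degrees

# grid first-arrival solver agrees with the closed form
env <- environment_make(c(8.4, 8), list(make_rhombus(1.2, 0.9, c(4.2, 3))))
fld <- solve_arrival(env, v = 0.2, a_eik = 0.03, y0_front = 1)
indent_from_front(front_from_arrival(fld, 3))      # 0.2408 vs formula 0.2505

# stochastic expansion around a disk, with genealogy
cfg <- eden_config(W = 150L, R = 20L, config = "single")
sim <- eden_run(cfg, seed = 3)
sim                                     # <fo_eden> W = 150, 22573 events, ...
detect_pinned_boundary(sim)$pinned      # TRUE: sector boundary at obstacle top
fo  <- genealogy(sim)
length(fo$roots)                        # 6 founding lineages feed the front
```

The numbers mean: the kink appears 1.5 mm beyond the obstacle's widest
point; by `d = 8` mm the indent has healed to ≈ 0.09 mm ≈ `w²/2d`; the grid
solver reproduces the closed-form indent to within a third of a grid cell at
this coarse spacing; and of 150
founding genotypes only 6 lineages still feed the frontier after the
expansion — drift plus the obstacle prune the rest.

A thin command-line wrapper over the same functions ships in
`inst/cli/frontsim.R` (subcommands `env`, `eikonal`, `fkpp`, `eden`,
`stats`, `fixtures`).

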