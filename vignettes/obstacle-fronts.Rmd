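---
title: "Population fronts around growth-free obstacles: models and methods"
author: "frontobstacles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population fronts around growth-free obstacles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontobstacles)
```

# The problem

When a population expands into new territory — phage plaques spreading across
a bacterial lawn, microbial colonies crossing a plate, macroscopic invasions
around lakes — the habitat is rarely uniform. This package studies the
simplest heterogeneity: a compact **obstacle**, a region where the population
cannot reproduce, embedded in a growth-permitting habitat (the "lake
scenario", growth-permitting area fraction $\rho$ close to 1). Two questions
drive the design:

1. **Front shape.** How does an obstacle distort an initially planar
   population front, and how does the distortion heal downstream?
2. **Genetic structure.** How does the distortion reshape the genetic
   composition of the expanding population — which genotypes die, which
   sweep, and what do the genealogies of frontier individuals look like?

Three engines answer these at different levels of description, sharing one
geometry layer (`environment_make()`, `make_rhombus()`, `make_circle()`,
`make_random_field()`).

# Constant-speed (eikonal) model

The most minimal description: the front advances at constant speed $v$ in
its local normal direction, and an obstacle simply deletes the front segment
that would overlap it (no pushing, no flow). This is a Huygens construction,
equivalent to solving the eikonal equation $|\nabla T| = 1/v$ for the first
arrival time $T$ with obstacle cells excluded.

Closed forms for a rhombus of half-width $w$ and half-height $h$ centered on
the propagation axis:

* beyond the widest point the shadow is filled by **circular arcs** of
  radius $d$ (the front position beyond the point of maximal width) centered
  at the max-width corners, meeting the obstacle edge at **90°**
  (`front_rhombus()`, `contact_angle()`);
* the arcs meet on the axis — a **kink** — once $d = \sqrt{w^2 + h^2}$
  (`kink_distance_rhombus()`);
* afterwards the indent (lag of the most retarded point behind the
  unperturbed front) is
  $\Delta(d) = d\,\bigl(1 - \sqrt{1 - w^2/d^2}\bigr) \to w^2/2d$,
  independent of $h$ (`indent_rhombus()`). Lengths rescaled by $w$ collapse
  the indent curves of all rhombi onto one master curve
  (`collapse_check()`); rescaling by $h$ does not.

For a disk of radius $r$ the shadow front is an envelope of arcs centered on
the boundary; the most retarded point solves a wrap-geodesic relation
(`circle_axis_lag()`), the kink is born as a cusp (opening angle zero) at
$d = \pi r/2$, and the far field heals with the same $w^2/2d$ law with
$w = r$: the long-range perturbation knows the obstacle's **width**, not its
shape. A thin tilted bar shows the same universality: its kink forms
off-center on the trailing side and drifts onto the bisecting normal
(`tilted_bar_kink_axis()`).

**Grid solver.** `solve_arrival()` implements fast marching on a rectangular
grid (spacing `a_eik`, default $w/100$; obstacle cells are those whose
center falls in a closed obstacle polygon). The upwind update is second
order where two accepted neighbors are available, falling back to first
order. The first-order scheme is exact for planar fronts in any direction
but accumulates $O(a\ln(d/a))$ error along the rarefaction fan emanating
from an obstacle corner — enough to threaten the two-cell agreement we
require against the closed forms over $d \in [d_\text{kink}, 10w]$; the
second-order scheme keeps the measured indent error below one cell at all
tested resolutions (`order = 1` remains available for comparison).
`marker_path()` backtraces the steepest descent of $T$ with one-sided
(upwind) gradients so that on shock lines — e.g. the symmetry axis behind an
obstacle, where two characteristic families meet — the trace commits to one
characteristic instead of averaging them; exact ties resolve toward the
axis. Marker paths are the model's geodesics and predict the shape of
lineages behind the front.

Indent curves are measured by `indent_from_front()` as the gap between the
unperturbed front position (labeled from the lateral-edge columns, $d = 0$
at the obstacle's point of maximal width) and the curve minimum within a
lateral window of $\pm w$ around the symmetry axis. The window generalizes
the fixed-width crop used in plate assays; scaling it with $w$ keeps the
measurement equivariant under uniform rescaling of the geometry.

# Reaction-diffusion (FKPP) model

The constant-speed model ignores the finite width of a real front. The next
level is a generalized Fisher–Kolmogorov equation for the population density
$u(\mathbf{x}, t)$,

$$\partial_t u = D_\text{eff}\, \nabla^2 u
  + k_\text{eff}(\mathbf{x})\, u\,(K - u),$$

with $K = 1$ after rescaling and $k_\text{eff} = \hat k$ outside obstacles,
$0$ inside. Diffusion into the obstacle remains possible, so the obstacle
acts like an absorbing boundary with a depleted layer of width
$\xi = \sqrt{D_\text{eff}/\hat k}$ near its edge. A planar front travels at
the pulled speed $v = 2\sqrt{D_\text{eff}\hat k}$ set by its leading edge.

**Parameters.** The defaults are the phage-on-lawn estimates:
$D_\text{eff} = 0.0144\ \mathrm{mm^2/h}$ (a phage-in-agar proxy value) with
$v \approx 0.2$ mm/h observed, giving
$\hat k = v^2/4D_\text{eff} \approx 0.7/\mathrm{h}$
(`estimate_growth_rate()`). A Stokes–Einstein bound for a 60 nm virion in
water at 37 °C gives $0.04\ \mathrm{mm^2/h}$ (`stokes_einstein_D()`), about
a factor three larger — bracketing the plausible range. `fkpp_params()`
stores these with $\xi$ and the grid spacing.

**Numerics.** Space: square lattice of spacing $0.15\,\xi$, nine-point
Laplacian
$\nabla^2 u \approx [-20u + \sum_\text{corners} + 4\sum_\text{edges}]/(6a^2)$
(exact on quadratics), periodic lateral boundaries, and rows clamped to 1
behind / 0 ahead. Time: adaptive Adams method of lines
(`deSolve::ode(method = "adams")`, right-hand side in compiled code) with
`rtol = 1e-6`, `atol = 1e-8`; the absolute tolerance sits well below the
front threshold $u_\text{thresh} = 0.05$ so the leading edge stays resolved
and density bounds hold to the error control's roundoff. Halving either
tolerance moves extracted front positions by well under a tenth of a cell
(tested). The initial condition is a saturated region with a linear ramp of
width $2\xi$; it relaxes into the traveling profile within a few growth
times, and the obstacle is kept at least $10\,\xi$ ahead of the founding
line (violations are flagged).

The obstacle-free comoving profile agrees with the analytic approximation
$u(z) \approx (1+e^{z/c})^{-1} + \tfrac14 e^{z/c}(1+e^{z/c})^{-2}
\ln\!\bigl(4e^{z/c}(1+e^{z/c})^{-2}\bigr)$, $c = 2$, to a sup-norm of about
0.02 (we require 0.03; the formula is itself an approximation, and the
profile origin is aligned at the half-maximum crossing).

**What the comparison shows.** Extracted threshold fronts
(`extract_front()`, topmost crossing per column, obstacle cells masked,
$d$ labeled at the lattice edges) lag behind the constant-speed prediction
at every $d$ (`lag_vs_eikonal()`): the depleted boundary layer and the
slowdown of highly curved front elements (radius $\lesssim \xi$) both delay
the wrapped front. Both effects live on the scale $\xi$, so the lag shrinks
as $D_\text{eff}$ decreases at fixed $v$ ($\xi \propto \sqrt{D}$) — the
constant-speed model is the $L \gg \xi$ limit.

# Stochastic Eden model with genotypes

Front-line number fluctuations — genetic drift — need individuals.
`eden_run()` implements an Eden growth variant on a hexagonal lattice
("pointy-top", odd rows offset half a unit; the neighbor convention is
documented in the code and is not fixed by the model): one individual per
site, a founding row of all-distinct genotypes, and per event a uniformly
chosen **frontier** site (occupied with at least one empty neighbor) copies
its genotype into a uniformly chosen empty neighbor. Individuals never die;
simulation time advances by $\mathrm{Exp}(1/|\text{frontier}|)$ per event.
Obstacles are disks of blocked sites (radius $R$, in units of the lattice
spacing); the lateral walls are blocked too (non-periodic, which keeps
genealogies planar for display). Blocked sites are excluded from the event
clock: counting them as choosable non-reproducers would only rescale time.
Default geometry mirrors the study conditions: width $W \approx 600$ sites,
$R \approx 80$, obstacle center $W/3$ ahead of the founding row and
laterally centered; the two-obstacle variant offsets the second disk by
$(5/3\,R, 5/2\,R)$. Runs stop once every site up to the stop depth (obstacle
top $+\,3R$ by default) is filled. The event loop is compiled; a full
default-scale run is a fraction of a second, and R's own RNG stream makes
`set.seed()` reproduce runs bit for bit.

Every site records its parent and birth time, so `genealogy()` reconstructs
the lineage forest of any frontier set exactly (verified against replaying
the event log from scratch on small lattices — `eden_replay()`).
`sector_boundaries()`, `detect_pinned_boundary()` and
`classify_lineage_route()` quantify the genetic consequences:

* genotypes meeting the obstacle head-on are trapped and lost;
* the genotypes grazing the obstacle's flanks inherit its shadow — an
  inflationary sweep we quantify by comparing their final-frontier
  abundance against a same-seed obstacle-free run (geometry-enhanced
  genetic drift). The enrichment holds in the majority of seeds but not
  every one: drift can still extinguish a grazing sector after the sweep.
* the two grazing sectors meet at the obstacle top and leave a **pinned
  boundary** there. For a symmetric single obstacle the boundary sits within
  $\pm R/8$ of the axis (the operator's default window). For the staggered
  pair, the first obstacle's shadow delays one approach and the meeting
  point sits measurably off-axis (about $R/4$–$R/3$ at $R = 40$), so the
  pair analysis inspects the second obstacle's top half-width; the flanking
  sectors must still trace to opposite sides of the obstacle through their
  parent pointers.

# Synthetic environments

`make_random_field()` places $N$ non-overlapping features of linear size $L$
uniformly at random (rejection sampling, seeded). The feature shape is not
fixed by the habitat classification $(\rho, N, L)$; axis-aligned squares are
the default with disks as an option. Since $\rho$ is determined by $N$, $L$
and the domain area, the realized growth fraction is computed from exact
polygon areas and must agree with the requested target within 2%
(relative); infeasible packings fail with an explicit error after a bounded
number of attempts. Monte-Carlo point sampling of generated fields agrees
with the exact areas to well under 1%.

# Problem sizes used in the shipped tests

The test suite exercises the full printed geometries where that is what is
being claimed (the four rhombi at grid spacing $w/100$; ten seeded Eden runs
at $W = 300$, $R = 40$ for the two-obstacle pinning count, which keeps the
printed $W/R$ aspect while completing in seconds; the FKPP lag comparison at
the printed $D_\text{eff}$, $\hat k$, $w = 1.2$, $h = 0.9$ on a domain with
lateral margins of $5w$). In the diffusivity-sensitivity comparison
($D \to D/3$ at fixed $v$), $\xi$ shrinks threefold and the $0.15\,\xi$
lattice would make that arm about $27\times$ the cost of the main arm, so it
runs at the parameter set's upper-bound spacing $0.2\,\xi$ with the founding
line $10\,\xi$ below the obstacle in each arm and fronts sampled over
$d \in [2.0, 2.9]$ mm (past kink formation and past the closure of the
wrapped reaction-diffusion front); the lag separation between the arms is an
order of magnitude above the discretization error, so the comparison is
insensitive to this choice. Elsewhere the suite uses deliberately small
geometries for unit checks
(e.g. $\xi = 0.1$ mm parameter sets on millimeter-scale domains). Quasi-1D
planar runs use a four-column periodic lattice, which is exactly the planar
problem under the nine-point stencil.

# What the synthetic conditions do and do not show

The generators emulate the modeled system: deterministic growth-free
obstacles with sharp boundaries, homogeneous growth elsewhere, no death, no
selection, no front instabilities. Passing tests therefore demonstrate the
internal consistency of the three models and their mutual limits (eikonal as
the $\xi \to 0$ limit of FKPP; Eden sharing the constant-speed geometry on
average), not agreement with any particular wet-lab system: real lawns have
soft obstacle edges, growth-rate gradients, front chirality and
stationary-phase slowdowns that none of the engines represent. The
experimental image-analysis pipeline of plate assays is out of scope; the
indent operator reuses only its definition (distance between the most
lagging front point and the unperturbed front position).

# Numerical edge cases and tie-breaks

* Obstacle polygons are **closed sets**; a grid cell is an obstacle cell iff
  its center is inside — deterministic rasterization shared by both grid
  engines, so lag comparisons see identical geometry.
* Circles are stored as inscribed 360-gons; the area deficit is
  $O(n^{-2})$ (0.005% at the default) and `w_half` is reported as $r$.
* Closed-form arcs are discretized at 0.5° per vertex; kink-formation
  scans are therefore resolved to about one arc step of front travel.
* Contact angles on discretized fronts are measured by extrapolating a
  parabola fitted 3–15 cells away from the contact (the staircase next to
  the mask corrupts closer vertices).
* Eden event ties cannot occur (continuous clock); frontier bookkeeping is
  incremental and exact, which the replay oracle checks.
* `indent_from_front()` clamps negative indents (overshoot) to zero and
  records the excess in an attribute.

# Known limitations

* The eikonal solver assumes isotropic speed; no curvature corrections, no
  anisotropy, no visibility-graph exactness (the grid error bound stands in).
* The FKPP solver is explicit-in-spirit (non-stiff Adams); very fine grids
  are diffusion-stability limited, so halving the spacing quadruples cost.
* The Eden engine fixes one lattice orientation; lattice anisotropy of Eden
  growth is not corrected for and is visible in front roughness statistics.
* Genealogy statistics at the printed scale are qualitative by design (ten
  seeds), matching how such simulations are interpreted; the package reports
  counts, not confidence intervals.
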