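---
title: "Programming cluster shapes with diffusible growth regulators: model and methods"
author: "protrusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Programming cluster shapes with diffusible growth regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(protrusim)
```

## The model

`protrusim` simulates how a two-dimensional cluster of identical cells can
grow into rods, cones, or multi-fingered shapes when the cells regulate
their growth through secreted diffusible chemicals. The model couples three
ingredients.

**Chemical fields.** Every cell can secrete up to $q$ chemicals. Because
secretion, diffusion and degradation are much faster than growth, each
concentration field is at quasi-static equilibrium with the current cluster
shape $\Omega$:
$$\nabla^2 c_i + \mu_i(\mathbf{c}) - \gamma_i c_i = 0,$$
with $c_i \to 0$ far from the cluster, and the source $\mu_i$ supported on
$\Omega$. All quantities are rescaled: lengths by the decay length
$\sqrt{D/\gamma}$ of the reference chemical, concentrations by the growth
threshold they act at, so each scheme is controlled by a handful of
dimensionless numbers (secretion rates $\tilde\mu$, threshold ratios
$\tilde K_s$, degradation ratios $\gamma_r$).

**Regulation.** Secretion and growth are gated by Hill functions
$H(c \mid K, n) = c^n/(K^n + c^n)$ with $|n| = 100$, i.e. effectively
sharp thresholds ($n<0$: inhibition, $n>0$: activation, $n=0$: no
participation, which evaluates to exactly 1). The local growth rate is the
product of the growth-link gates, with a maximum of 1 — this sets the time
unit. Two further regulation modes exist: a chemical can scale another's
*maximum secretion rate* by $\max(1 + \tilde b\,c, 0)$ with $\tilde b \le 0$,
and a chemical can *lower a growth threshold* linearly,
$K_\text{eff} = K\,\max(1 - c, 0)$ (the threshold-regulator circuit; the
clamp at zero is ours — a negative concentration threshold is meaningless).

**Tissue flow.** The cluster is an incompressible cellular fluid: cell
division acts as a volume source, $\nabla\cdot\mathbf{u} = g$, with Darcy
flow $\mathbf{u} = -\nabla P$ and $P = 0$ on the boundary. The boundary
then advances with the outward normal speed $u_n = -\partial P/\partial n$.

Named circuits (`named_scheme()`) cover the canonical regimes: no
regulation (clusters round up), a single growth inhibitor (a rod of
constant width grows from a tip-localized growth zone), two growth
inhibitors (the growth zone can split, giving up to three protrusions), a
growth-threshold regulator (cones that sharpen and stop autonomously), a
growth-activator variant, and feedforward inhibitor cascades of length $q$
(each added inhibitor can split existing growth zones again, which is why
the attainable protrusion number scales like $3 \cdot 2^{q-2}$).

## Numerical methods

**Geometry.** The boundary is a closed counterclockwise polygon of marker
points (front tracking), resampled every step to a target spacing
$h = 0.05$ along a periodic cubic spline. Spline (rather than chord-linear)
resampling matters: linear resampling shaves every convex corner by
$O(\kappa h^3)$ per step, which accumulates over hundreds of steps into a
visible mass loss. The interior is covered by a uniform grid of cell size
$h_\text{mesh} = 0.05$ clipped exactly to the polygon (interior cells carry
weight $h_\text{mesh}^2$ at their centers; boundary cells carry the clipped
area at the clipped centroid), so quadrature weights sum to the polygon
area to machine precision and grid adjacency gives cheap connected
components and point location. The mesh is rebuilt from the polygon every
step; nothing is advected.

**Fields.** Each chemical is solved by Green's-function quadrature on the
unbounded plane, $c(\mathbf{x}) = \sum_j w_j \mu_j \,
K_0(\sqrt{\gamma_r}\,|\mathbf{x}-\mathbf{x}_j|)/2\pi$, with the singular
self term replaced by the analytic mean of the kernel over a disk of the
element's area. Chemicals are solved in topological order of the secretion
dependencies (cyclic circuits are rejected; every scheme here is
feedforward). On a uniformly sourced disk the solution matches the
closed-form Bessel profile within 1% at the default resolution and within
0.2% at a refined one (the tested bounds; typical errors are much smaller).

Threshold gates are evaluated with *sub-cell anti-aliasing*: near a
secretion or growth interface, a cell contributes the estimated fraction of
its area on the active side (linear reconstruction from grid-neighbor
gradients) instead of a 0/1 nodal value. This removes the $O(h)$ staircase
bias of nodal thresholding, which is the accuracy bottleneck in regimes
where a growth-zone arc sits within a few percent of threshold.

**Flow.** The pressure problem is solved with a boundary-integral method:
the Newtonian potential of the growth field provides the particular
solution, and a single-layer density $\sigma$ on the boundary enforces
$P=0$ through Symm's first-kind equation (midpoint panels; analytic
integration of the log kernel over the panel itself and its near
neighbors). By Green's second identity the representation vanishes
identically outside the cluster, so $u_n = \sigma$ directly, and the total
flux constraint $\oint \sigma \, ds = \int_\Omega g \, dA$ is imposed as an
augmentation row. This keeps the system solvable when the contour's
logarithmic capacity equals 1 (the unit disk!) and makes the discrete
divergence theorem exact by construction. A single pass of a
$(\tfrac14,\tfrac12,\tfrac14)$ filter removes the grid-scale ripple that
first-kind systems amplify out of quadrature noise; the flux total is
restored exactly afterwards. Disk oracles ($u_n = R/2$ for uniform growth;
$u_n = a^2/2R$ for a concentric patch) hold within the tested 1% bound,
including the capacity-one unit disk.

**Time stepping.** Forward Euler on the marker points with an adaptive step
$dt = \alpha h / \max u_n$, $\alpha = 0.3$, additionally capped by
$0.025/\max(\kappa u_n)$ so the curvature term of the swept area — the
second-order correction $\tfrac12 \kappa u_n^2 dt^2$ — stays near 1% of the
per-step area increment at sharp tips. A step whose advected polygon
self-intersects is retried with half the step (up to ten times). Per-step
mass balance $|\Delta A - dt \int g\,dA| / \Delta A$ is tested to stay
below 2% on every accepted step and in practice stays below 1% in all
shipped scenarios. Runs stop at the time
horizon, when the growth zone vanishes (below one mesh cell), when the
boundary is static, or when the protrusion count has been constant over the
trailing 20% of elapsed time.

**Study region.** Protrusions are studied at the cluster front: growth is
masked behind the fixed lab-frame plane $x = x_0/2$ through the initial
cluster's midpoint. The same mask is applied to the sources of *regulated*
chemicals (those gated by secretion links), while constitutive secretion is
global. The reason is a boundary-layer artifact of the idealized initial
shape: at the sharp back corners of the parabola the inhibitor
concentration dips below threshold in slivers of area $\sim 0.01$, which
would otherwise switch on downstream secretion far from the tip; their
far-field contribution (several percent of the front concentration of the second
chemical) is enough to flip threshold-marginal growth-zone morphology. In
the modeled biology the regulated programs belong to the active front;
the quiescent back maintains only its baseline secretion.

## Shape measurements

Protrusions are counted as local maxima of the centroid-to-boundary
distance (a cyclic signal) with topographic prominence above half the
initial cluster width, restricted to the growing region when a mask is
active — the static back corners of the initial shape are geometric
features, not protrusions. The count is stable under boundary resampling.
Widths are measured perpendicular to the protrusion axis at stations
behind the tip; trajectories are classified `multi` / `cone` / `rod` /
`round` from the final count, the late-time width trend, and whether the
growth zone vanished. Growth-zone statistics threshold the growth field at
$1/2$ (the midpoint of the near-step gates, so the choice is insensitive)
and count connected components by grid adjacency; component counting agrees
with an independent pixel flood fill at twice the resolution.

## Choices made where the design was open, and known limitations

* **Initial parabola.** $y(x) = \pm\tfrac{y_0}{2}\sqrt{(x_0-x)/x_0}$ with
  the apex at $(x_0, 0)$ and a straight vertical back at $x = 0$ — the
  unique parabola with the stated length and width and a flat back end.
  The sharp corners where the back meets the flanks are rounded at the
  $h$ scale by the first resampling; see the back-corner discussion above
  for their one real side effect.
* **Problem sizes.** Default runs use $h = h_\text{mesh} = 0.05$, boundary
  markers $\sim 150$–$400$, mesh nodes $\sim 400$–$3000$, a few hundred
  steps per scenario; a single-inhibitor rod to $t = 24$ takes tens of
  seconds on one core. These resolve the disk oracles to $\lesssim 1\%$ and
  keep whole scenario families runnable in minutes.
* **Cut experiments.** Regeneration cuts remove the tip side of the
  cluster: a straight cut leaves a flat end with two sharp corners; an
  elliptical cut replaces the tip by a smooth convex cap. The cap's
  semi-axes are chosen so its apex curvature matches the natural rod-tip
  curvature — the mechanistic reason a curved cut regenerates a single
  protrusion is precisely that the natural tip stays curved throughout
  growth. A much blunter cap behaves like a flat end and can regrow two
  fingers.
* **Threshold-marginal regimes are knife-edged.** In the two-inhibitor
  circuit at $\tilde K_s = 1$ the second inhibitor's concentration along
  the front of the growth zone sits within a few percent of threshold over
  a wide range of $\tilde\mu_{Y0}$ (at $t=0$ it scales exactly linearly in
  $\tilde\mu_{Y0}$, because the secretion support depends only on $c_X$).
  Whether the zone's front arc is alive — and hence whether a *middle*
  protrusion grows before the side arms take over — can flip within that
  margin. In this implementation the canonical
  $(\tilde\mu_X, \tilde\mu_{Y0}, \tilde K_s, \gamma_r) = (8, 65, 1, 1)$
  run robustly produces the two side protrusions while the middle advances
  only as a broad transient bulge whose prominence stays well below the
  counting threshold of $0.5$, so the package reports two protrusions
  there; the three-protrusion capacity of the circuit family is
  demonstrated by the zone-splitting measurements and the cascade
  construction. Component counts at the hole-to-split transition
  ($\tilde\mu_{Y0} \approx 60$) are similarly resolution-sensitive: the
  converged zone at 60 is a connected ring with a center hole, and the
  first lateral break appears near 65.
* **Out of scope.** Topology changes of the cluster (merging/splitting),
  three-dimensional clusters, multiple cell types, mechanics beyond Darcy
  flow, and time-dependent (non-quasi-static) chemical kinetics.

## What the simulations do and do not show

All inputs are synthetic: the initial shapes are idealized conic sections
and the circuits are exact threshold logic. Passing scenarios therefore
demonstrate the *mechanisms* — tip-localized growth zones elongate rods,
zone splitting multiplies protrusions, threshold regulation sharpens and
terminates cones, cut geometry steers regeneration — under clean
conditions. They do not show robustness to cellular noise, to graded
(low-$|n|$) regulation, or to mechanical effects absent from Darcy flow.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config("fig3_muX8")      # single growth inhibitor, mu = 8
tr  <- run_growth(cfg)
summary(tr)
plot(tr)                                  # boundary snapshots, early to late
classify_shape(tr)                        # "rod"
```
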