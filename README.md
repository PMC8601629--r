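# protrusim

Simulating how cell clusters can be *programmed* to grow into different
shapes using diffusible signals.

A central question of synthetic developmental biology is how simple the
rules encoded in a single cell type can be while still producing a desired
tissue morphology. `protrusim` implements a 2D model in which every cell
may secrete diffusible chemicals that regulate growth: each concentration
field is at quasi-static reaction–diffusion equilibrium with the current
cluster shape Ω,

    ∇²cᵢ + μᵢ(c) − γᵢ cᵢ = 0,   cᵢ → 0 far from the cluster,

secretion and growth are gated by sharp Hill thresholds
H(c | K, n) = cⁿ/(Kⁿ + cⁿ) with |n| = 100, and the cluster expands as an
incompressible cellular fluid (Darcy flow):

    ∇·u = g,   u = −∇P,   P = 0 on ∂Ω,

so the boundary advances with the outward normal speed uₙ = −∂P/∂n. All
quantities are rescaled (lengths by the reference chemical's decay length,
concentrations by growth thresholds), leaving a handful of dimensionless
parameters per circuit.

With these ingredients the package reproduces the canonical outcomes of the
model family: unregulated clusters round up; a single growth inhibitor
grows a constant-width **rod** from a tip-localized growth zone; a second,
secretion-gated inhibitor can split the growth zone and grow **multiple
protrusions**; a growth-threshold regulator produces sharpening **cones**
that stop growing autonomously; cut clusters **regenerate** one or two
protrusions depending on the cut geometry; and feedforward inhibitor
cascades scale the attainable protrusion number like 3·2^(q−2).

The numerical core is a front-tracking boundary (periodic-spline
remeshing), free-space Green's-function quadrature for the fields
(modified-Helmholtz kernel K₀), and a boundary-integral (Symm single-layer)
solver for the Darcy pressure whose discrete flux balance is exact by
construction. See the methods vignette (`vignettes/growth-circuits.Rmd`)
for the model, the numerics, and the design decisions.

## Worked example: a rod from a single growth inhibitor

```r
library(protrusim)
tr <- run_growth(scenario_config("fig3_muX8"))   # inhibitor secretion rate 8
summary(tr)
```

```
Growth run [single_inhibitor], stopped: t_max after 174 steps (t = 24.000)
  final area 1.7073, growth zone 0.0262, 1 protrusion(s), class: rod
  worst step mass-balance error 0.00681
```

The parabolic cluster (length 1.5, width 1) grows a single rod: its area
increases from 1.00 to 1.71 over 24 time units (time is measured in units
of the inverse maximal growth rate), the growth zone stays pinned at the
tip with a late-time area plateau of ≈ 0.024, and the minimum inhibitor
concentration on the front boundary plateaus at ≈ 0.90 — just below the
growth threshold of 1, which is what keeps the tip growing at constant
width. The protrusion counter finds one tip at (2.66, 0):

```r
count_protrusions(tr$final_curve, prominence = 0.5, xmin = 0.75)$tips
#>       x y height prominence
#> 1 2.664 0  1.492      1.246
```

Other entry points: `named_scheme()` builds the regulatory circuits,
`solve_circuit_fields()` / `solve_boundary_velocity()` expose the field and
flow solvers, `apply_cut()` performs regeneration cuts,
`growth_zone_stats()`, `width_profile()` and `classify_shape()` quantify
the shapes, and `write_trajectory()` / `read_trajectory()` archive runs as
plain CSV/JSON with checksums. `list_scenarios()` names all shipped
scenario configurations. A thin command-line wrapper lives at
`inst/cli/protrusim.R`:

```sh
Rscript inst/cli/protrusim.R run --scenario fig3_muX8 --out out/
Rscript inst/cli/protrusim.R analyze --traj out/
```

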