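---
title: "Methods: strain-energy-driven bone remodeling in 2D mandible sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-energy-driven bone remodeling in 2D mandible sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneadapt)
```

## The model

Bone remodeling is modeled as a fixed-point iteration between linear
elasticity and a density-update rule. The state variable is the apparent
density $\rho$ (g/cm$^3$) of each trabecular element, clamped to
$[0.1, 2.2]$ — the lower bound prevents non-physical vanishing stiffness,
the upper bound is the apparent density of cortical bone. Density sets
stiffness through the cubic power law

$$E = C\,\rho^3, \qquad C = 3790\ \mathrm{MPa\,cm^9/g^3},$$

an empirical relation for trabecular bone. All other tissues (enamel,
dentin, pulp, cementum, periodontal ligament, gingiva, cortical bone)
are linear elastic and isotropic with fixed constants; cortical bone is
deliberately *not* remodeled, the standard simplification for sectioned
models without masticatory muscle forces.

Each iteration solves plane-stress elastostatics on the quadrilateral
mesh under per-tooth loads (100 N vertical, 10 N lateral-mesial, split
equally over a small node set at each crown apex), computes the element
strain energy density $U = \tfrac12\,\sigma:\varepsilon$, forms the
stimulus $S = U/\rho$ (J/g), and updates all trabecular elements
simultaneously (a Jacobi-style sweep, matching the solve-then-update
structure of the iteration):

$$\Delta\rho =
\begin{cases}
0 & (1-\delta)S_0 \le S \le (1+\delta)S_0\\
\big(S-(1+\delta)S_0\big)\,B\Delta t & S > (1+\delta)S_0\\
\big(S-(1-\delta)S_0\big)\,B\Delta t & S < (1-\delta)S_0
\end{cases}
\qquad |\Delta\rho| \le 0.05\,\rho .$$

The equilibrium ("lazy") zone and the $\pm5\%$ saturation of the change
rate are the rule's two stabilizing ingredients; both are needed to avoid
the checkerboard instability of pure site-wise adaptation. The upper and
lower saturation thresholds are not independent parameters here: the rule
is implemented as the linear branches *clipped* to $\pm 0.05\rho$, the
unique continuous completion of the five-branch description. A
discontinuous variant (fixed thresholds with a jump to the constant rate)
would behave identically except on the measure-zero transition stimuli,
but the continuous reading is the one consistent with "change of density
mandated to be at most 5%".

In the mm–N–MPa unit system 1 MPa of energy density is exactly
1 J/cm$^3$, so $S = U/\rho$ comes out in J/g with no conversion factors;
this fixes the unit conventions of every interface in the package.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `S0` | 0.008 | J/g | reference stimulus; sets the density scale at equilibrium, $\rho^* \sim (\sigma^2/2CS_0)^{1/4}$ |
| `delta` | 0.15 | — | equilibrium-zone half-width (fraction of `S0`) |
| `BdT` | 2 | g$^2$/(J cm$^3$) | linear branch slope; only the product of rate constant and time step matters |
| `saturation_fraction` | 0.05 | — | cap on per-iteration change as a fraction of $\rho$ |
| `rho_min`, `rho_max` | 0.1, 2.2 | g/cm$^3$ | density clamps |
| `convergence_tol` | 0.0003 | — | relative mean-density change, checked over the last two steps |
| `max_iter` | 80 | — | iteration cap; headline fields are conventionally read at iteration 80 |
| `vertical`, `lateral` | −100, 10 | N | per-tooth occlusal load |
| `thickness` | 0.6 | mm | plane-stress out-of-plane thickness (see below) |

Note an asymmetry built into the rule: the growth branch can always reach
its $+0.05\rho$ cap, but the loss branch is bounded by
$(1-\delta)S_0\,B\Delta t = 0.0136$ g/cm$^3$ per iteration regardless of
how small $S$ is (for $\rho > 0.27$ the $-5\%$ cap is never active).
Descents from dense starts are therefore intrinsically slow: a 2.2 start
cannot shed more than about 1.1 g/cm$^3$ in 80 iterations.

## Synthetic geometry

No anatomical geometry is shipped; the cross section is generated
parametrically. Three teeth (canine, lateral incisor, central incisor) or
one tooth are placed 8 mm apart on a 24 mm × 30 mm domain: an elliptical
enamel-capped crown with a dentin body and pulp chamber above a 2 mm
gingival band, a linearly tapered root (dentin with a pulp canal) wrapped
by 0.25 mm cementum and a 0.3 mm periodontal ligament, a 2 mm cortical
shell across the bottom, trabecular fill elsewhere. Meshing is
*rasterized*: a structured grid of square 4-node quads covers the domain,
each cell takes the tissue label of its centroid, and cells outside the
anatomy are dropped. This guarantees positively-oriented, well-shaped
elements and bit-deterministic meshes with no mesh-generator dependency;
the price is stair-stepped tissue interfaces, acceptable because the
results of interest are trends in element-averaged fields, not interface
stresses.

The domain and default element size (0.15 mm at full resolution) were
sized so the mesh budget matches full-scale anterior-section models:
about 29,000 elements in total of which roughly a third are trabecular.
A 24 mm-wide snug domain is what makes that proportion attainable — on a
wider rectangle the trabecular fill dominates the element count no matter
how the teeth are drawn. Sub-element-scale layers (PDL, cementum) simply
rasterize to the nearest label; their share of elements stabilizes under
refinement (verified in the tests as a sub-5-percentage-point change per
mesh halving).

What the generator does *not* emulate: real root/crown outlines, the
curved inferior border of the mandible, cancellous micro-architecture,
multi-rooted teeth, and any patient-specific variation. Passing trend
tests on this geometry therefore demonstrates properties of the
*algorithm*, not anatomical fidelity of any particular field.

## Plane thickness calibration

The out-of-plane thickness of a 2D plane-stress section is a free
modeling choice that scales every stress linearly and every energy
density quadratically; no printed value pins it down. It is calibrated
once, as follows, and then left alone: at the default uniform
0.8 g/cm$^3$ start under the default loads, the large majority (about
90% on the reference mesh) of trabecular elements must carry a stimulus
*above* the equilibrium zone, so that the early iterations proceed at
the saturated growth rate — the qualitative operating regime the
underlying study reports for its default configuration. The coarsest
thickness satisfying this on the reference mesh is 0.6 mm, which is
also anatomically sensible for an incisor-region section and places the
closed-form density scale $(\sigma^2/2CS_0)^{1/4}$ in the
1.5–1.7 g/cm$^3$ range. With the 1 mm thickness that would otherwise be
the neutral default, the model instead starts *near* its equilibrium and
the adaptation dynamics are qualitatively different. Thickness remains a
config knob (`load: thickness:`), and absolute density magnitudes should
always be read as conditional on it.

## Numerical choices

* **Elements.** Bilinear quads, full 2×2 Gauss quadrature, plane-stress
  constitutive matrix. Near-incompressible soft tissues (pulp
  $\nu=0.49$, PDL/gingiva $\nu=0.45$) may lock mildly; they are thin,
  not remodeled, and their stiffness is 2–3 orders below the hard
  tissues, so no selective reduced integration is used.
* **Element energy.** $U$ is the volume-weighted Gauss average of
  $\tfrac12\sigma:\varepsilon$, computed as $\tfrac12 u_e^TK_eu_e/V_e$,
  which makes the global work–energy identity
  $\sum_e U_eV_e = \tfrac12 f^Tu$ hold to round-off (asserted at 1e-8 in
  the tests). Stress/strain records are centroid values.
* **Solver.** The mesh is congruent rectangles, so the element stiffness
  is $E_e$ times one reference matrix per distinct Poisson ratio, and
  assembly is a fixed-pattern triplet fill. The reduced symmetric system
  is solved by sparse Cholesky; the symbolic analysis is reused across
  remodeling iterations (only trabecular moduli change). Reaction
  balance is verified at 1e-8 relative every solve.
* **Loads.** Each tooth's force is split equally over the three mesh
  nodes nearest its crown apex; a single-node point load would create a
  mesh-dependent singularity in the stimulus field. Verification
  problems that need exact uniform tractions pass explicit consistent
  nodal forces instead.
* **Convergence and reporting.** A run stops when the mean trabecular
  density changes by less than `convergence_tol` over two consecutive
  steps. Because an out-of-zone start approaches the stationary set
  asymptotically, a converged bar run sits within the tolerance-implied
  slack $|S-\text{edge}| \le \text{tol}\cdot\rho/B\Delta t$ of the
  closed-form window — the acceptance test derives its bounds from that
  slack rather than pretending exact attainment. For *parametric
  sweeps* the package's reference protocol disables early stopping
  (tol $10^{-9}$) and compares all runs at the common 80th iteration:
  comparing runs frozen at different early-stop times conflates the
  parameter effect with stopping-time variation, and visibly distorts
  the extreme-area-fraction trends.
* **Degenerate inputs.** Zero loads short-circuit to the zero field;
  meshes without a bottom node set are rejected as singular before
  factorization; inverted elements are reported by element; ties in
  load-node selection break deterministically by distance then
  x-coordinate.
* **Problem sizes.** The test tier uses a 0.8 mm mesh (~1,000 elements)
  for unit tests and the committed reference configuration — 0.45 mm,
  3,253 elements, 1,158 trabecular — for trend suites; these sizes make
  the whole battery run in a couple of minutes while staying fine enough
  for stable trends.

## Diagnostics

`checkerboard_index()` quantifies the classical instability of density
adaptation: the mean absolute density difference across edge-adjacent
trabecular pairs, normalized by the field range (0 for uniform fields, 1
for perfect min/max alternation). With both stabilizers active the
default reference run stays well below the committed regression bound of
0.2. `field_similarity()` (one minus mean absolute difference over the
clamp range, maskable to element subsets) and
`extreme_area_fractions()` (shares of elements at $\rho\le0.3$ and
$\rho\ge2.0$, the near-clamp color-map bands) summarize final fields for
the sweep comparisons.

## Known limitations

* The lazy zone makes fixed points non-unique, and the loss branch's
  rate cap makes descents slow. On this rectangular synthetic geometry,
  whose margins away from the load paths carry little stress, runs
  started from different uniform densities keep a larger spread at
  iteration 80 (about 24% of the initial spread on the reference
  configuration) than the 15% contraction the original study observed —
  path-dependent load redistribution parks different element sets at
  the upper clamp, and low-stress margins retain memory of dense
  starts. This is a property of geometry plus rule, and the
  corresponding acceptance expectation is left failing rather than
  retuned.
* The constrained-vs-free boundary-condition comparison concentrates
  its differences along the distal edge at all heights; the bottom half
  of the trabecular region is shielded by the always-fixed bottom and
  the cortical shell and ends up about as similar between the two modes
  as the peri-root band, so the "agreement only near the teeth"
  ordering does not reproduce here (similarities 0.88 both, ordering
  reversed by ~0.005). The band width (2 mm) was fixed before
  measurement and kept.
* Absolute densities are conditional on the plane-thickness choice;
  only trends and verification problems are meaningful at desk scale.
* No contact or PDL nonlinearity, no loading-history stimulus, no
  cortical remodeling, no 3D effects.
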