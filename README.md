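# boneadapt

Iterative finite-element simulation of load-adaptive trabecular bone
remodeling in 2D tooth–mandible cross sections.

Trabecular bone adapts its apparent density to the mechanical demand placed
on it. Under chewing and biting loads the strain energy density per unit
bone mass acts as the remodeling stimulus: where it exceeds a reference
level bone is deposited, where it falls short bone is resorbed, and inside
an equilibrium ("lazy") zone around the reference nothing happens. This
package implements that coupled mechanics–adaptation loop for a stylized
distal–mesial section of an anterior mandible carrying one or three teeth,
and provides the parametric sweep machinery (boundary conditions, initial
density, reference stimulus, equilibrium-zone width) used to study the
algorithm's convergence, stability and uniqueness. It is aimed at
researchers in computational bone biomechanics and at anyone studying the
numerical behavior of density-based adaptation rules.

## Model

Each trabecular element carries an apparent density
`rho` (g/cm^3), clamped to [0.1, 2.2], which sets its Young's modulus via
the density power law

    E = C * rho^3,          C = 3790 MPa cm^9/g^3.

Plane-stress linear elasticity is solved on a structured 4-node
quadrilateral mesh (teeth with enamel/dentin/pulp, cementum and PDL
wrapping the roots, gingiva, a 2 mm cortical shell at the mandible bottom,
trabecular fill) under per-tooth occlusal loads of 100 N vertical plus
10 N lateral. The element strain energy density `U = (1/2) sigma : eps`
(MPa, equal to J/cm^3 in the mm–N–MPa unit system) yields the stimulus

    S = U / rho             (J/g),

and each iteration updates every trabecular element simultaneously:

    drho = 0                                  if (1-d) S0 <= S <= (1+d) S0
    drho = (S - (1+d) S0) * B dt              above the zone
    drho = (S - (1-d) S0) * B dt              below the zone
    |drho| <= 0.05 * rho                      (saturated change rate)

with defaults `S0 = 0.008 J/g`, half-width `d = 0.15`,
`B dt = 2 g^2/(J cm^3)`. The loop stops when the mean trabecular density
changes by less than 0.03% over two consecutive iterations, or after 80
iterations.

## Worked example

```r
library(boneadapt)

mesh <- mandible_mesh(geometry_params(element_size = 0.5))
mesh
#> <bone_mesh> 2787 nodes, 2646 elements (918 trabecular), h = 0.5 mm
#>   node sets: bottom, left_edge, right_edge, load_nodes

res <- run_simulation(mesh)   # defaults: rho0 = 0.8, constrained edges
res
#> <bone_remodeling> 918 trabecular elements, converged after 66 iterations
#>   mean density 0.800 -> 1.340 g/cm^3, eq-zone occupancy 22.3%

glance(res)
#>   iterations converged mean_density min_density max_density eq_zone_fraction
#> 1         66 TRUE              1.34         0.1         2.2            0.223
```

The run starts from a uniform 0.8 g/cm^3 field whose stimulus lies mostly
above the equilibrium zone, so the mean density climbs at the saturated
+5%-per-iteration rate early on, then levels off as elements enter the
zone or hit the clamps; density accumulates between the tooth roots and
toward the mesial (loaded) side. `tidy(res)` returns the per-iteration
trajectory, `autoplot(res)` plots it, and
`plot_density_field(mesh, res$final_density)` maps the final field.

Sweeping the reference stimulus reproduces the study's central trend —
a higher reference value demands more energy per unit mass to sustain
bone, so the structure converges to a lower average density:

```r
sw <- run_sweep(sweep_spec("reference_stimulus", values = c(0.004, 0.008, 0.012),
                           mesh = mesh))
tidy(sw)[, c("value", "iterations", "mean_density", "low_fraction", "high_fraction")]
#>   value iterations mean_density low_fraction high_fraction
#> 1 0.004         80         1.65       0             0.233
#> 2 0.008         66         1.34       0.0403        0.0839
#> 3 0.012         46         1.14       0.0643        0.0272
```

`low_fraction`/`high_fraction` are the shares of trabecular elements in
the near-clamp "blue" (rho <= 0.3) and "red" (rho >= 2.0) bands.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/scripts/boneadapt.R run   --config my.yaml --out-dir out
Rscript inst/scripts/boneadapt.R sweep --param reference_stimulus --out-dir out
Rscript inst/scripts/boneadapt.R mesh  --out-dir out
```

Configuration files are YAML/JSON with `geometry:`, `materials:`,
`remodeling:`, `load:`, `simulation:` and `output:` blocks; omitted keys
take the package defaults, unknown keys are rejected.

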