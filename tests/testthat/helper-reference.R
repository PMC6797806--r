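# Shared fixtures, memoised so expensive reference runs are computed once
# per test session.

.ref_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.ref_cache[[name]])) {
    assign(name, force(expr), envir = .ref_cache)
  }
  .ref_cache[[name]]
}

# Reference configuration for trend checks: 3-tooth mesh at 0.45 mm
# (~3,000 elements) and a fixed 80-iteration protocol (the convergence
# check effectively disabled) so runs are compared at a common iteration,
# mirroring the study's at-the-80th-iteration reporting.
ref_mesh <- function() {
  memo("ref_mesh", mandible_mesh(geometry_params(element_size = 0.45)))
}

ref_params <- function() remodeling_params(convergence_tol = 1e-9)

ref_sweep <- function(parameter) {
  memo(paste0("sweep_", parameter),
       run_sweep(sweep_spec(parameter, mesh = ref_mesh(),
                            params = ref_params())))
}

ref_run <- function() {
  memo("ref_run",
       run_simulation(ref_mesh(), params = ref_params(),
                      snapshots = c(0, 1, 10, 80)))
}

# Coarse 3-tooth mesh for cheap unit tests.
small_mesh <- function() {
  memo("small_mesh", mandible_mesh(geometry_params(element_size = 0.8)))
}

# Single-material trabecular bar with nu = 0, giving an exactly uniaxial
# state under an end load; sigma = |force| / (width * thickness).
uniaxial_bar <- function(width = 1, height = 10, element_size = 1) {
  bar_mesh(width, height, element_size)
}

nu0_materials <- function() {
  material_table(list(trabecular = list(poisson_ratio = 0)))
}

# Consistent nodal forces for a uniform vertical traction sigma (MPa) on
# the top edge of a bar mesh: edge nodes take half the tributary width.
consistent_top_traction <- function(mesh, sigma, thickness) {
  top <- mesh$node_sets$load_nodes[[1]]
  xs <- mesh$nodes$x[top]
  trib <- rep(mesh$hx, length(top))
  trib[xs %in% range(xs)] <- mesh$hx / 2
  tibble::tibble(node = top, fx = 0, fy = sigma * trib * thickness)
}
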