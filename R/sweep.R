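#' Specify a one-parameter sweep
#'
#' One simulation per value of a single swept parameter, all other
#' parameters held at the study defaults. The default value grids are the
#' study's own: uniform initial density 0.2 to 2.0 g/cm^3 in steps of 0.2;
#' initial perturbations of 0.5, 1, 2 and 5 percent about 0.8 g/cm^3;
#' reference stimulus 0.002 to 0.014 J/g in steps of 0.002; equilibrium
#' half-widths 5 to 45 percent in steps of 10; and the two side-edge
#' boundary-condition modes.
#'
#' @param parameter One of `"initial_density"`, `"initial_perturbation"`,
#'   `"reference_stimulus"`, `"equilibrium_half_width"`, `"bc_mode"`.
#' @param values Values to sweep; `NULL` selects the default grid above.
#' @param mesh A tagged `"bone_mesh"`; the same mesh is used for every
#'   run.
#' @param materials,load,params Base configuration shared by all runs.
#' @param seed Integer seed (used by the perturbation sweep's random
#'   draws; recorded for all sweeps).
#' @param snapshots Snapshot iterations passed to [run_simulation()].
#' @return A list of class `"sweep_spec"`.
#' @export
sweep_spec <- function(parameter = c("initial_density", "initial_perturbation",
                                     "reference_stimulus",
                                     "equilibrium_half_width", "bc_mode"),
                       values = NULL,
                       mesh = mandible_mesh(),
                       materials = material_table(),
                       load = load_case(),
                       params = remodeling_params(),
                       seed = 1L,
                       snapshots = c(0, 80)) {
  parameter <- match.arg(parameter)
  if (is.null(values)) {
    values <- switch(parameter,
      initial_density = seq(0.2, 2.0, by = 0.2),
      initial_perturbation = c(0.005, 0.01, 0.02, 0.05),
      reference_stimulus = seq(0.002, 0.014, by = 0.002),
      equilibrium_half_width = seq(0.05, 0.45, by = 0.10),
      bc_mode = c("constrained", "free"))
  }
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  structure(list(parameter = parameter, values = values, mesh = mesh,
                 materials = materials, load = load, params = params,
                 seed = as.integer(seed), snapshots = snapshots),
            class = "sweep_spec")
}

#' Run a parametric sweep
#'
#' Runs [run_simulation()] once per sweep value and summarizes the final
#' fields: converged/final mean density and the area fractions of the
#' highest-density and lowest-density trabecular elements.
#'
#' @param spec A [sweep_spec()].
#' @param low_threshold,high_threshold Density thresholds (g/cm^3) for the
#'   lowest/highest-density area fractions (defaults 0.3 and 2.0, bands
#'   near the clamps).
#' @return A list of class `"bone_sweep"`: `summary` (tibble with one row
#'   per value: `parameter`, `value`, `iterations`, `converged`,
#'   `mean_density`, `low_fraction`, `high_fraction`, `checkerboard`,
#'   thresholds), `results` (list of `"bone_remodeling"` runs) and the
#'   `spec`.
#' @examples
#' \donttest{
#' mesh <- mandible_mesh(geometry_params(element_size = 1))
#' sw <- run_sweep(sweep_spec("equilibrium_half_width", c(0.05, 0.45),
#'                            mesh = mesh))
#' sw$summary
#' }
#' @export
run_sweep <- function(spec, low_threshold = 0.3, high_threshold = 2.0) {
  stopifnot(inherits(spec, "sweep_spec"))
  runs <- vector("list", length(spec$values))
  for (i in seq_along(spec$values)) {
    v <- spec$values[[i]]
    args <- list(mesh = spec$mesh, materials = spec$materials,
                 load = spec$load, params = spec$params,
                 snapshots = spec$snapshots, seed = spec$seed)
    switch(spec$parameter,
      initial_density = { args$initial_density <- as.numeric(v) },
      initial_perturbation = {
        args$initial_density <- 0.8
        args$perturbation <- as.numeric(v)
      },
      reference_stimulus = {
        args$params <- do.call(remodeling_params,
                               modifyList(unclass(spec$params),
                                          list(S0 = as.numeric(v))))
      },
      equilibrium_half_width = {
        args$params <- do.call(remodeling_params,
                               modifyList(unclass(spec$params),
                                          list(delta = as.numeric(v))))
      },
      bc_mode = {
        args$load <- load_case(vertical = spec$load$vertical,
                               lateral = spec$load$lateral,
                               bc_mode = as.character(v),
                               thickness = spec$load$thickness)
      },
      stop("unknown sweep parameter: ", spec$parameter, call. = FALSE))
    runs[[i]] <- do.call(run_simulation, args)
  }

  summ <- purrr::map2_dfr(runs, spec$values, function(r, v) {
    fr <- extreme_area_fractions(r$final_density, low_threshold,
                                 high_threshold)
    g <- glance(r)
    tibble::tibble(parameter = spec$parameter, value = v,
                   iterations = g$iterations, converged = g$converged,
                   mean_density = g$mean_density,
                   low_fraction = fr[["low_fraction"]],
                   high_fraction = fr[["high_fraction"]],
                   checkerboard = g$checkerboard,
                   low_threshold = low_threshold,
                   high_threshold = high_threshold)
  })
  structure(list(summary = summ, results = runs, spec = spec),
            class = "bone_sweep")
}

#' @export
print.bone_sweep <- function(x, ...) {
  cat(sprintf("<bone_sweep> %s over %d values\n",
              x$spec$parameter, length(x$spec$values)))
  print(x$summary)
  invisible(x)
}

#' @rdname run_sweep
#' @param x A `"bone_sweep"` object.
#' @param ... Unused.
#' @method tidy bone_sweep
#' @export
tidy.bone_sweep <- function(x, ...) x$summary

#' Similarity between two density fields
#'
#' `1 - mean(|a - b|) / (rho_max - rho_min)` over a masked element
#' subset: 1 for identical fields, 0 for fields at opposite clamps
#' everywhere. Used to quantify where two runs (e.g. constrained vs free
#' boundary conditions) agree.
#'
#' @param field_a,field_b Density fields on identical meshes (same length
#'   and element order).
#' @param mask Logical or integer subset of elements to compare; default
#'   all.
#' @param rho_min,rho_max Density clamps defining the normalization range.
#' @return Scalar in `[0, 1]`.
#' @export
field_similarity <- function(field_a, field_b, mask = NULL,
                             rho_min = 0.1, rho_max = 2.2) {
  if (length(field_a) != length(field_b)) {
    stop("fields differ in length; are they on the same mesh?",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- seq_along(field_a)
  if (is.logical(mask) && length(mask) != length(field_a)) {
    stop("logical `mask` must match the field length", call. = FALSE)
  }
  a <- field_a[mask]
  b <- field_b[mask]
  if (!length(a)) stop("empty mask", call. = FALSE)
  1 - mean(abs(a - b)) / (rho_max - rho_min)
}

#' Area fractions of extreme-density trabecular bone
#'
#' Fractions of elements with density at or below `low_threshold` and at
#' or above `high_threshold`, the "blue" and "red" bands of a density
#' color map.
#'
#' @param field Density per trabecular element, g/cm^3.
#' @param low_threshold,high_threshold Thresholds in g/cm^3, low < high.
#' @return Named numeric vector `c(low_fraction, high_fraction)`.
#' @examples
#' extreme_area_fractions(rep(0.8, 10), 0.3, 2.0)  # c(0, 0)
#' @export
extreme_area_fractions <- function(field, low_threshold = 0.3,
                                   high_threshold = 2.0) {
  if (low_threshold >= high_threshold) {
    stop("`low_threshold` must be below `high_threshold`", call. = FALSE)
  }
  c(low_fraction = mean(field <= low_threshold),
    high_fraction = mean(field >= high_threshold))
}

#' Trabecular element masks for regional comparisons
#'
#' `mask_peri_root()` selects trabecular elements whose centroid lies
#' within `width` mm of any PDL element (the band around the tooth
#' roots); `mask_bottom_half()` selects trabecular elements in the lower
#' half of the trabecular region.
#'
#' @param mesh A `"bone_mesh"`.
#' @param width Band width around the roots, mm (default 2).
#' @return Logical vector over the trabecular elements (mesh order).
#' @export
mask_peri_root <- function(mesh, width = 2) {
  el <- mesh$elements
  cx <- (el$col - 0.5) * mesh$hx
  cy <- (el$row - 0.5) * mesh$hy
  trab <- el$region == "trabecular"
  pdl <- el$region == "pdl"
  if (!any(pdl)) stop("mesh has no PDL elements", call. = FALSE)
  tx <- cx[trab]; ty <- cy[trab]
  px <- cx[pdl]; py <- cy[pdl]
  near <- rep(FALSE, sum(trab))
  for (k in seq_along(px)) {
    near <- near | ((tx - px[k])^2 + (ty - py[k])^2 <= width^2)
    if (all(near)) break
  }
  near
}

#' @rdname mask_peri_root
#' @export
mask_bottom_half <- function(mesh) {
  el <- mesh$elements
  cy <- (el$row - 0.5) * mesh$hy
  trab <- el$region == "trabecular"
  cy_t <- cy[trab]
  cy_t <= (min(cy_t) + max(cy_t)) / 2
}
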