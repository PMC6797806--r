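#' Run the iterative bone remodeling simulation
#'
#' Alternates finite-element solves with density updates: assign each
#' trabecular element its modulus from the current apparent density, solve
#' plane-stress elasticity under the chewing/biting loads, convert strain
#' energy density to the stimulus S = U/rho, apply the lazy-zone update
#' rule simultaneously to all trabecular elements, clamp, and repeat until
#' the mean trabecular density stabilizes or `max_iter` updates have been
#' applied.
#'
#' @param mesh A tagged `"bone_mesh"` with at least one trabecular
#'   element.
#' @param materials A [material_table()].
#' @param load A [load_case()].
#' @param params A [remodeling_params()].
#' @param initial_density Uniform initial apparent density, g/cm^3
#'   (default 0.8).
#' @param perturbation Half-width of a uniform random multiplicative
#'   perturbation applied per element to the initial density (e.g. 0.01
#'   for +-1 percent; default 0, no perturbation).
#' @param seed Integer seed for the perturbation draw; required when
#'   `perturbation > 0` so runs are reproducible.
#' @param snapshots Iteration numbers at which full density and stimulus
#'   fields are stored (default `c(0, 1, 5, 10, 20, 50, 80)`).
#'
#' @return A list of class `"bone_remodeling"`:
#'   * `trajectory`: tibble with one row per iteration — `iteration`,
#'     `mean_density`, `min_density`, `max_density` (g/cm^3),
#'     `eq_zone_fraction` (share of trabecular elements whose stimulus
#'     lies in the equilibrium zone), `checkerboard`
#'     (see [checkerboard_index()]);
#'   * `final_density`, `final_stimulus`: per-trabecular-element fields at
#'     the last recorded iteration;
#'   * `snapshots`: named list `iter<k>` of tibbles (`element`, `density`,
#'     `stimulus`);
#'   * `termination`: list with `reason` (`"converged"` or `"max_iter"`)
#'     and `iterations` (number of updates applied);
#'   * `mesh`, `params`, `load`, `initial_density`, `perturbation`,
#'     `seed`.
#' @examples
#' mesh <- bar_mesh(1, 10, 1)
#' res <- run_simulation(mesh, load = load_case(vertical = -5, lateral = 0),
#'                       initial_density = 0.3)
#' res$termination
#' tail(tidy(res))
#' @export
run_simulation <- function(mesh, materials = material_table(),
                           load = load_case(),
                           params = remodeling_params(),
                           initial_density = 0.8, perturbation = 0,
                           seed = NULL,
                           snapshots = c(0, 1, 5, 10, 20, 50, 80)) {
  stopifnot(inherits(mesh, "bone_mesh"), inherits(params, "remodeling_params"))
  trab <- which(mesh$elements$region == "trabecular")
  if (!length(trab)) stop("mesh has no trabecular elements", call. = FALSE)

  rho <- rep(initial_density, length(trab))
  if (perturbation > 0) {
    if (is.null(seed)) {
      stop("a `seed` is required when `perturbation` > 0", call. = FALSE)
    }
    rho <- withr::with_seed(as.integer(seed), {
      rho * (1 + stats::runif(length(trab), -perturbation, perturbation))
    })
  }
  rho <- pmin(pmax(rho, params$rho_min), params$rho_max)

  ctx <- fem_context(mesh, materials, load)
  lo <- (1 - params$delta) * params$S0
  hi <- (1 + params$delta) * params$S0

  rows <- vector("list", params$max_iter + 1L)
  snaps <- list()
  mean_hist <- numeric(0)
  reason <- "max_iter"
  iterations <- params$max_iter
  S <- NULL

  for (it in 0:params$max_iter) {
    sol <- tryCatch(
      assemble_and_solve(mesh, materials, rho, load, context = ctx),
      error = function(e) stop("FE solve failed at iteration ", it, ": ",
                               conditionMessage(e), call. = FALSE))
    S <- stimulus(sol$elements$U[trab], rho, rho_min = params$rho_min)

    m <- mean(rho)
    mean_hist <- c(mean_hist, m)
    rows[[it + 1L]] <- tibble::tibble(
      iteration = it, mean_density = m,
      min_density = min(rho), max_density = max(rho),
      eq_zone_fraction = mean(S >= lo & S <= hi),
      checkerboard = checkerboard_index(mesh, rho))
    if (it %in% snapshots) {
      snaps[[paste0("iter", it)]] <- tibble::tibble(
        element = mesh$elements$element[trab], density = rho, stimulus = S)
    }
    if (convergence_check(mean_hist, params$convergence_tol)) {
      reason <- "converged"
      iterations <- it
      break
    }
    if (it == params$max_iter) break
    rho <- apply_update(rho, density_increment(rho, S, params), params)
  }

  structure(
    list(trajectory = dplyr::bind_rows(rows[!vapply(rows, is.null, TRUE)]),
         final_density = rho, final_stimulus = S,
         snapshots = snaps,
         termination = list(reason = reason, iterations = iterations),
         mesh = mesh, params = params, load = load,
         materials = materials,
         initial_density = initial_density,
         perturbation = perturbation, seed = seed),
    class = "bone_remodeling")
}

#' @export
print.bone_remodeling <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "<bone_remodeling> %d trabecular elements, %s after %d iterations\n",
    length(x$final_density), x$termination$reason, x$termination$iterations))
  cat(sprintf("  mean density %.3f -> %.3f g/cm^3, eq-zone occupancy %.1f%%\n",
              tr$mean_density[1], utils::tail(tr$mean_density, 1),
              100 * utils::tail(tr$eq_zone_fraction, 1)))
  invisible(x)
}

#' Convergence test on the mean-density history
#'
#' TRUE when the relative change of the mean trabecular density is below
#' `tol` for the last two consecutive iteration steps.
#'
#' @param mean_density_history Numeric vector of per-iteration means.
#' @param tol Relative tolerance (default 0.0003, i.e. 0.03 percent).
#' @return Logical scalar.
#' @examples
#' convergence_check(c(1.000, 1.0002, 1.0003), 0.0003)  # TRUE
#' convergence_check(c(1.0, 1.1, 1.1001), 0.0003)       # FALSE
#' @export
convergence_check <- function(mean_density_history, tol = 0.0003) {
  n <- length(mean_density_history)
  if (n < 3) return(FALSE)
  m <- mean_density_history[(n - 2):n]
  ch <- abs(diff(m)) / m[1:2]
  all(ch < tol)
}

#' Checkerboard instability index
#'
#' Mean absolute density difference across edge-adjacent trabecular
#' element pairs, normalized by the field's density range: 0 for a uniform
#' field, 1 for perfect min/max alternation on a grid. Large values flag
#' the discontinuous checkerboard patterns that unstable remodeling rules
#' can produce.
#'
#' @param mesh A `"bone_mesh"`.
#' @param density_field Density per trabecular element (mesh order).
#' @return Non-negative scalar.
#' @export
checkerboard_index <- function(mesh, density_field) {
  trab <- mesh$elements$region == "trabecular"
  if (length(density_field) != sum(trab)) {
    stop("`density_field` must have one value per trabecular element",
         call. = FALSE)
  }
  el <- mesh$elements[trab, , drop = FALSE]
  key <- function(col, row) paste(col, row)
  idx <- stats::setNames(seq_len(nrow(el)), key(el$col, el$row))
  right <- idx[key(el$col + 1L, el$row)]
  up <- idx[key(el$col, el$row + 1L)]
  pairs_a <- c(seq_len(nrow(el))[!is.na(right)], seq_len(nrow(el))[!is.na(up)])
  pairs_b <- c(right[!is.na(right)], up[!is.na(up)])
  if (!length(pairs_a)) {
    stop("no edge-adjacent trabecular element pairs", call. = FALSE)
  }
  rng <- diff(range(density_field))
  if (rng == 0) return(0)
  mean(abs(density_field[pairs_a] - density_field[pairs_b])) / rng
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a remodeling run into its per-iteration trajectory
#'
#' @param x A `"bone_remodeling"` object.
#' @param ... Unused.
#' @return The trajectory tibble (one row per iteration).
#' @method tidy bone_remodeling
#' @export
tidy.bone_remodeling <- function(x, ...) x$trajectory

#' One-row summary of a remodeling run
#'
#' @param x A `"bone_remodeling"` object.
#' @param ... Unused.
#' @return A one-row tibble: `iterations`, `converged`, final
#'   `mean_density`, `min_density`, `max_density`, `eq_zone_fraction`
#'   and `checkerboard`.
#' @method glance bone_remodeling
#' @export
glance.bone_remodeling <- function(x, ...) {
  last <- utils::tail(x$trajectory, 1)
  tibble::tibble(
    iterations = x$termination$iterations,
    converged = x$termination$reason == "converged",
    mean_density = last$mean_density,
    min_density = last$min_density,
    max_density = last$max_density,
    eq_zone_fraction = last$eq_zone_fraction,
    checkerboard = last$checkerboard)
}
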