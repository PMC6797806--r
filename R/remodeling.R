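#' Remodeling rule parameters
#'
#' Parameters of the density-update rule: the reference stimulus, the
#' equilibrium ("lazy") zone half-width, the linear remodeling rate, the
#' saturation cap on per-iteration change, the density clamps, and the
#' convergence settings of the iterative loop.
#'
#' @param S0 Reference mechanical stimulus in J/g (default 0.008).
#' @param delta Equilibrium-zone half-width as a fraction of `S0`
#'   (default 0.15): no density change while the stimulus lies in
#'   `[(1 - delta) * S0, (1 + delta) * S0]`.
#' @param BdT Linear-branch remodeling rate times time step, in
#'   g^2/(J cm^3) (default 2).
#' @param saturation_fraction Cap on the per-iteration density change as a
#'   fraction of the current density (default 0.05, i.e. +-5 percent).
#' @param rho_min,rho_max Density clamps in g/cm^3 (defaults 0.1 and 2.2,
#'   the apparent density of cortical bone).
#' @param convergence_tol Relative change of the mean trabecular density
#'   below which the loop stops, checked over the last two consecutive
#'   iterations (default 0.0003, i.e. 0.03 percent).
#' @param max_iter Maximum number of density updates (default 80).
#'
#' @return A list of class `"remodeling_params"`.
#' @examples
#' remodeling_params()
#' remodeling_params(S0 = 0.004, delta = 0.25)
#' @export
remodeling_params <- function(S0 = 0.008, delta = 0.15, BdT = 2,
                              saturation_fraction = 0.05,
                              rho_min = 0.1, rho_max = 2.2,
                              convergence_tol = 0.0003, max_iter = 80L) {
  stopifnot(is.numeric(S0), length(S0) == 1L, S0 > 0,
            is.numeric(delta), length(delta) == 1L, delta > 0, delta < 1,
            is.numeric(BdT), length(BdT) == 1L, BdT > 0,
            is.numeric(saturation_fraction), length(saturation_fraction) == 1L,
            saturation_fraction > 0, saturation_fraction < 1,
            is.numeric(rho_min), rho_min > 0,
            is.numeric(rho_max), rho_max > rho_min,
            is.numeric(convergence_tol), convergence_tol > 0,
            max_iter >= 1)
  structure(
    list(S0 = S0, delta = delta, BdT = BdT,
         saturation_fraction = saturation_fraction,
         rho_min = rho_min, rho_max = rho_max,
         convergence_tol = convergence_tol, max_iter = as.integer(max_iter)),
    class = "remodeling_params"
  )
}

#' @export
print.remodeling_params <- function(x, ...) {
  cat("<remodeling_params>\n")
  cat(sprintf("  S0 = %g J/g, delta = %g, BdT = %g g^2/(J cm^3)\n",
              x$S0, x$delta, x$BdT))
  cat(sprintf("  saturation +-%g%% of rho, clamps [%g, %g] g/cm^3\n",
              100 * x$saturation_fraction, x$rho_min, x$rho_max))
  cat(sprintf("  convergence tol %g over last two steps, max %d iterations\n",
              x$convergence_tol, x$max_iter))
  invisible(x)
}

#' Mechanical stimulus: strain energy density per unit bone mass
#'
#' S = U / rho, in J/g when U is in MPa (= J/cm^3) and rho in g/cm^3.
#'
#' @param U Strain energy density per element, MPa.
#' @param rho Apparent density per element, g/cm^3; must be at or above the
#'   lower clamp.
#' @param rho_min Lower clamp used to validate `rho` (default 0.1).
#' @return Stimulus in J/g, same length as `U`.
#' @examples
#' stimulus(0.0064, 0.8)  # 0.008 J/g, the default reference value
#' @export
stimulus <- function(U, rho, rho_min = 0.1) {
  if (length(U) != length(rho)) {
    stop("`U` and `rho` must have the same length", call. = FALSE)
  }
  if (any(rho < rho_min - 1e-12)) {
    stop("density below the lower clamp; clamping must be applied upstream",
         call. = FALSE)
  }
  U / rho
}

#' Per-iteration density change
#'
#' Five-branch remodeling rule: no change inside the equilibrium zone,
#' linear growth/loss with slope `BdT` outside it, and saturation of the
#' change magnitude at `saturation_fraction * rho` far from the zone. The
#' saturation thresholds are realized implicitly by clipping the linear
#' branches, the unique continuous completion of the rule.
#'
#' @param rho Current apparent density, g/cm^3.
#' @param S Mechanical stimulus, J/g (same length as `rho`).
#' @param params A [remodeling_params()] object.
#' @return Density change Delta-rho in g/cm^3, elementwise.
#' @examples
#' p <- remodeling_params()
#' density_increment(1, 0.008, p)   # 0: S at the reference value
#' density_increment(1, 0.0102, p)  # 0.002: linear growth branch
#' density_increment(1, 0.5, p)     # 0.05: saturated at 5% of rho
#' @export
density_increment <- function(rho, S, params = remodeling_params()) {
  stopifnot(inherits(params, "remodeling_params"))
  if (length(S) != length(rho)) {
    stop("`rho` and `S` must have the same length", call. = FALSE)
  }
  lo <- (1 - params$delta) * params$S0
  hi <- (1 + params$delta) * params$S0
  drho <- numeric(length(S))
  up <- S > hi
  dn <- S < lo
  drho[up] <- (S[up] - hi) * params$BdT
  drho[dn] <- (S[dn] - lo) * params$BdT
  cap <- params$saturation_fraction * rho
  pmin(pmax(drho, -cap), cap)
}

#' Apply a density update with clamping
#'
#' Simultaneous (Jacobi-style) update of every trabecular element,
#' rho <- clamp(rho + drho, rho_min, rho_max). The input field is not
#' modified.
#'
#' @param rho Density field, g/cm^3.
#' @param drho Increments from [density_increment()], same length.
#' @param params A [remodeling_params()] object supplying the clamps.
#' @return The updated density field.
#' @export
apply_update <- function(rho, drho, params = remodeling_params()) {
  stopifnot(inherits(params, "remodeling_params"))
  if (length(rho) != length(drho)) {
    stop("`rho` and `drho` must have the same length", call. = FALSE)
  }
  pmin(pmax(rho + drho, params$rho_min), params$rho_max)
}
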