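#' Default material table for the tooth-mandible model
#'
#' Isotropic linear-elastic constants for each tissue region. All regions
#' except trabecular bone carry a fixed Young's modulus; trabecular bone
#' instead carries the power-law constant `C` and gets its modulus from the
#' current apparent density via [modulus_from_density()].
#'
#' @param overrides Optional named list, keyed by region name, of lists with
#'   any of `youngs_modulus` (MPa), `poisson_ratio`, and (trabecular only)
#'   `C` (MPa cm^9/g^3).
#'
#' @return A tibble with columns `region`, `youngs_modulus` (MPa, `NA` for
#'   trabecular), `poisson_ratio`, and `C` (`NA` except trabecular).
#'
#' @details Units are fixed as mm-N-MPa throughout the package, so a strain
#'   energy density of 1 MPa is identically 1 J/cm^3 and the remodeling
#'   stimulus U/rho comes out in J/g with density in g/cm^3.
#'
#' @examples
#' material_table()
#' material_table(list(trabecular = list(poisson_ratio = 0.0)))
#' @export
material_table <- function(overrides = NULL) {
  tab <- tibble::tibble(
    region = c("enamel", "dentin", "pulp", "cementum", "pdl",
               "gingiva", "cortical", "trabecular"),
    youngs_modulus = c(79600, 18600, 150, 13700, 200, 200, 13700, NA_real_),
    poisson_ratio = c(0.3, 0.31, 0.49, 0.3, 0.45, 0.45, 0.3, 0.3),
    C = c(rep(NA_real_, 7), 3790)
  )
  if (!is.null(overrides)) {
    if (!is.list(overrides) || is.null(names(overrides))) {
      stop("`overrides` must be a named list keyed by region", call. = FALSE)
    }
    bad <- setdiff(names(overrides), tab$region)
    if (length(bad)) {
      stop("unknown material region(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (reg in names(overrides)) {
      ov <- overrides[[reg]]
      allowed <- if (reg == "trabecular") c("poisson_ratio", "C") else
        c("youngs_modulus", "poisson_ratio")
      bad_f <- setdiff(names(ov), allowed)
      if (length(bad_f)) {
        stop("region '", reg, "': cannot override ",
             paste(bad_f, collapse = ", "), call. = FALSE)
      }
      i <- which(tab$region == reg)
      for (f in names(ov)) tab[[f]][i] <- ov[[f]]
    }
  }
  validate_material_table(tab)
  tab
}

validate_material_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("region", "youngs_modulus", "poisson_ratio", "C") %in%
                  names(tab)))
  fixed <- tab$region != "trabecular"
  if (any(!is.finite(tab$youngs_modulus[fixed])) ||
      any(tab$youngs_modulus[fixed] <= 0)) {
    stop("all fixed-region moduli must be positive", call. = FALSE)
  }
  if (any(tab$poisson_ratio < 0 | tab$poisson_ratio >= 0.5)) {
    stop("Poisson ratios must satisfy 0 <= nu < 0.5", call. = FALSE)
  }
  Ct <- tab$C[tab$region == "trabecular"]
  if (!is.finite(Ct) || Ct <= 0) {
    stop("trabecular law constant C must be positive", call. = FALSE)
  }
  invisible(tab)
}

#' Trabecular modulus-density power law
#'
#' Nominal Young's modulus of trabecular bone as a cubic function of apparent
#' density, E = C * rho^3.
#'
#' @param rho Apparent density in g/cm^3; must be strictly positive
#'   (upstream clamping keeps simulated densities at or above 0.1 g/cm^3).
#' @param C Law constant in MPa cm^9/g^3 (default 3790).
#'
#' @return Nominal modulus in MPa, same length as `rho`.
#' @examples
#' modulus_from_density(1.0)  # 3790
#' modulus_from_density(0.8)  # 1940.48
#' @export
modulus_from_density <- function(rho, C = 3790) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0)) {
    stop("`rho` must be strictly positive and finite", call. = FALSE)
  }
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("`C` must be a single positive number", call. = FALSE)
  }
  C * rho^3
}

#' Elastic constants for one element
#'
#' Returns the (E, nu) pair an element receives given its region label and,
#' for trabecular bone, its current apparent density.
#'
#' @param region A single region label.
#' @param rho Apparent density in g/cm^3; required iff `region` is
#'   `"trabecular"`, ignored otherwise.
#' @param table A material table, see [material_table()].
#'
#' @return A named list with `youngs_modulus` (MPa) and `poisson_ratio`.
#' @examples
#' material_for_element("enamel")
#' material_for_element("trabecular", rho = 1.0)
#' @export
material_for_element <- function(region, rho = NULL, table = material_table()) {
  i <- match(region, table$region)
  if (is.na(i)) stop("unknown region: ", region, call. = FALSE)
  if (identical(region, "trabecular")) {
    if (is.null(rho)) {
      stop("trabecular elements require a density `rho`", call. = FALSE)
    }
    list(youngs_modulus = modulus_from_density(rho, table$C[i]),
         poisson_ratio = table$poisson_ratio[i])
  } else {
    if (!is.null(rho)) rho <- NULL  # density only drives trabecular bone
    list(youngs_modulus = table$youngs_modulus[i],
         poisson_ratio = table$poisson_ratio[i])
  }
}

# Vectorised per-element (E, nu) used by the FE assembly.
element_materials <- function(mesh, table, density) {
  reg <- mesh$elements$region
  i <- match(reg, table$region)
  if (anyNA(i)) {
    stop("mesh contains region labels missing from the material table",
         call. = FALSE)
  }
  E <- table$youngs_modulus[i]
  trab <- reg == "trabecular"
  if (any(trab)) {
    if (is.null(density) || length(density) != sum(trab)) {
      stop("`density` must supply one value per trabecular element",
           call. = FALSE)
    }
    E[trab] <- modulus_from_density(density, table$C[match("trabecular", table$region)])
  }
  list(E = E, nu = table$poisson_ratio[i])
}
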