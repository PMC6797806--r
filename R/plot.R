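#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Density or stimulus map on the element grid
#'
#' Tile map of a per-trabecular-element field at the element centroids,
#' with non-trabecular regions drawn in grey and the fill scale fixed to
#' the density clamps so panels from different iterations are comparable.
#'
#' @param mesh A `"bone_mesh"`.
#' @param field Values for the trabecular elements (mesh order).
#' @param rho_min,rho_max Fixed color-scale limits (the density clamps).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_density_field <- function(mesh, field, rho_min = 0.1, rho_max = 2.2,
                               title = "apparent density") {
  el <- mesh$elements
  df <- tibble::tibble(
    x = (el$col - 0.5) * mesh$hx,
    y = (el$row - 0.5) * mesh$hy,
    region = el$region,
    value = NA_real_)
  df$value[el$region == "trabecular"] <- field
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(data = df[is.na(df$value), ],
                       fill = "grey85",
                       width = mesh$hx, height = mesh$hy) +
    ggplot2::geom_tile(data = df[!is.na(df$value), ],
                       ggplot2::aes(fill = .data$value),
                       width = mesh$hx, height = mesh$hy) +
    ggplot2::scale_fill_viridis_c(limits = c(rho_min, rho_max),
                                  name = expression(rho ~ (g/cm^3))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Region map of a mesh
#'
#' @param mesh A `"bone_mesh"`.
#' @return A ggplot object with one fill per tissue region.
#' @export
plot_regions <- function(mesh) {
  el <- mesh$elements
  df <- tibble::tibble(
    x = (el$col - 0.5) * mesh$hx,
    y = (el$row - 0.5) * mesh$hy,
    region = factor(el$region, levels = region_labels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$region)) +
    ggplot2::geom_tile(width = mesh$hx, height = mesh$hy) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of a remodeling run
#'
#' Mean trabecular density (with min/max ribbon) and equilibrium-zone
#' occupancy versus iteration.
#'
#' @param object A `"bone_remodeling"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bone_remodeling
#' @export
autoplot.bone_remodeling <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trajectory,
    cols = c("mean_density", "eq_zone_fraction"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          mean_density = "mean density (g/cm^3)",
                          eq_zone_fraction = "equilibrium-zone fraction"))) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Sweep summary plot
#'
#' Final mean trabecular density against the swept parameter value.
#'
#' @param object A `"bone_sweep"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bone_sweep
#' @export
autoplot.bone_sweep <- function(object, ...) {
  s <- object$summary
  if (is.numeric(s$value)) {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$value,
                                    y = .data$mean_density)) +
      ggplot2::geom_line(color = "steelblue") +
      ggplot2::geom_point() +
      ggplot2::labs(x = object$spec$parameter,
                    y = "final mean density (g/cm^3)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$value),
                                    y = .data$mean_density)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = object$spec$parameter,
                    y = "final mean density (g/cm^3)") +
      ggplot2::theme_minimal()
  }
}
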