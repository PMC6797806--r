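#' All-defaults run configuration
#'
#' The nested configuration the rest of the package consumes: `geometry`,
#' `materials`, `remodeling`, `load`, `simulation`, `output` blocks plus a
#' top-level `seed`. Omitted keys in a config file take these defaults,
#' which are the study's default setting (constrained edges, uniform
#' 0.8 g/cm^3 initial density, reference stimulus 0.008 J/g, 15 percent
#' equilibrium half-width).
#'
#' @return A list of class `"bone_config"`.
#' @export
default_config <- function() {
  gp <- geometry_params()
  mt <- material_table()
  mats <- lapply(seq_len(nrow(mt)), function(i) {
    if (mt$region[i] == "trabecular") {
      list(poisson_ratio = mt$poisson_ratio[i], C = mt$C[i])
    } else {
      list(youngs_modulus = mt$youngs_modulus[i],
           poisson_ratio = mt$poisson_ratio[i])
    }
  })
  names(mats) <- mt$region
  structure(list(
    geometry = list(
      n_teeth = gp$n_teeth, domain_width = gp$domain_width,
      domain_height = gp$domain_height, crown_height = gp$crown_height,
      crown_half_width = gp$crown_half_width, root_length = gp$root_length,
      root_half_width = gp$root_half_width, root_taper = gp$root_taper,
      pdl_thickness = gp$pdl_thickness,
      cementum_thickness = gp$cementum_thickness,
      gingiva_thickness = gp$gingiva_thickness,
      cortical_bottom_thickness = gp$cortical_bottom_thickness,
      element_size = gp$element_size),
    materials = mats,
    remodeling = unclass(remodeling_params()),
    load = unclass(load_case()),
    simulation = list(initial_density = 0.8, perturbation = 0,
                      snapshots = c(0, 1, 5, 10, 20, 50, 80)),
    output = list(directory = "boneadapt-out",
                  formats = c("csv", "vtk", "png")),
    seed = 1L
  ), class = "bone_config")
}

config_blocks <- function() {
  c("geometry", "materials", "remodeling", "load", "simulation", "output",
    "seed")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by extension) configuration file, fills every
#' omitted key with the default from [default_config()], rejects unknown
#' keys, and validates parameter ranges by constructing the corresponding
#' parameter objects. An empty file yields the all-defaults
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"bone_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  as_bone_config(raw)
}

#' Coerce a nested list to a validated configuration
#'
#' @param raw A (possibly partial) nested configuration list.
#' @return A `"bone_config"` with defaults filled in.
#' @export
as_bone_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping/list", call. = FALSE)
  cfg <- unclass(default_config())
  bad <- setdiff(names(raw), config_blocks())
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (blk in names(raw)) {
    if (blk == "seed") { cfg$seed <- raw$seed; next }
    if (!is.list(raw[[blk]])) {
      stop("config block '", blk, "' must be a mapping", call. = FALSE)
    }
    if (blk == "materials") {
      # region-keyed overrides are validated by material_table() below
      for (reg in names(raw$materials)) {
        if (!reg %in% names(cfg$materials)) {
          stop("materials: unknown region '", reg, "'", call. = FALSE)
        }
        cfg$materials[[reg]] <- utils::modifyList(cfg$materials[[reg]],
                                                  raw$materials[[reg]])
      }
      next
    }
    bad_k <- setdiff(names(raw[[blk]]), names(cfg[[blk]]))
    if (length(bad_k)) {
      stop("config block '", blk, "': unknown key(s) ",
           paste(bad_k, collapse = ", "), call. = FALSE)
    }
    cfg[[blk]] <- utils::modifyList(cfg[[blk]], raw[[blk]])
  }
  cfg <- structure(cfg, class = "bone_config")
  validate_bone_config(cfg)
  cfg
}

validate_bone_config <- function(cfg) {
  # each constructor enforces its own invariants and names offenders
  do.call(geometry_params, cfg$geometry)
  config_materials(cfg)
  do.call(remodeling_params, cfg$remodeling)
  do.call(load_case, cfg$load)
  sim <- cfg$simulation
  stopifnot(sim$initial_density > 0, sim$perturbation >= 0,
            all(sim$snapshots >= 0))
  invisible(cfg)
}

config_materials <- function(cfg) {
  material_table(cfg$materials)
}

#' Run a simulation from a configuration
#'
#' Builds the mesh, materials, load case and remodeling parameters from a
#' `"bone_config"` and calls [run_simulation()].
#'
#' @param config A `"bone_config"` (see [load_config()],
#'   [default_config()]).
#' @param seed Optional integer overriding `config$seed`.
#' @return A `"bone_remodeling"` result with the config attached as
#'   attribute `"config"`.
#' @export
run_from_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "bone_config"))
  if (is.null(seed)) seed <- config$seed
  mesh <- mandible_mesh(do.call(geometry_params, config$geometry))
  res <- run_simulation(
    mesh,
    materials = config_materials(config),
    load = do.call(load_case, config$load),
    params = do.call(remodeling_params, config$remodeling),
    initial_density = config$simulation$initial_density,
    perturbation = config$simulation$perturbation,
    seed = seed,
    snapshots = config$simulation$snapshots)
  attr(res, "config") <- config
  res
}

#' Write a mesh or field snapshot as legacy ASCII VTK
#'
#' Unstructured-grid dialect readable by ParaView and VisIt: `POINTS`,
#' `CELLS` (0-based 4-node quads, type 9), optional `CELL_DATA` scalars
#' and `POINT_DATA` vectors.
#'
#' @param mesh A `"bone_mesh"`.
#' @param path Output file path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node 2-column matrices (written as
#'   3-vectors with z = 0) or numeric vectors (written as scalars).
#' @param title Dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list(),
                      title = "boneadapt field") {
  nd <- mesh$nodes
  el <- mesh$elements
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", title, "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d float", nrow(nd)))
  wl(sprintf("%.9g %.9g 0", nd$x, nd$y))
  wl(sprintf("CELLS %d %d", nrow(el), 5L * nrow(el)))
  wl(sprintf("4 %d %d %d %d", el$n1 - 1L, el$n2 - 1L, el$n3 - 1L,
             el$n4 - 1L))
  wl(sprintf("CELL_TYPES %d", nrow(el)))
  wl(as.character(rep(9L, nrow(el))))
  if (length(cell_data)) {
    wl(sprintf("CELL_DATA %d", nrow(el)))
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == nrow(el))
      wl(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default")
      wl(sprintf("%.9g", as.numeric(v)))
    }
  }
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", nrow(nd)))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) || is.data.frame(v)) {
        v <- as.matrix(v)
        stopifnot(nrow(v) == nrow(nd), ncol(v) == 2)
        wl(sprintf("VECTORS %s float", nm))
        wl(sprintf("%.9g %.9g 0", v[, 1], v[, 2]))
      } else {
        stopifnot(length(v) == nrow(nd))
        wl(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default")
        wl(sprintf("%.9g", as.numeric(v)))
      }
    }
  }
  invisible(path)
}

# density (and optionally stimulus) expanded from trabecular order to all
# elements, filler elsewhere
expand_trabecular <- function(mesh, field, fill = -1) {
  out <- rep(fill, nrow(mesh$elements))
  out[mesh$elements$region == "trabecular"] <- field
  out
}

#' Write run outputs and a manifest
#'
#' Writes the trajectory CSV, snapshot fields as legacy ASCII VTK,
#' density-map PNGs with a color scale fixed to the density clamps, a run
#' log, a config echo (when the result carries one), and a manifest of
#' all artifacts with MD5 checksums. A failed partial write leaves a
#' `.failed` marker file in the output directory.
#'
#' @param result A `"bone_remodeling"` run.
#' @param out_dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "vtk", "png")`.
#' @param mesh Mesh override; defaults to `result$mesh`.
#' @return A tibble manifest (`file`, `bytes`, `md5`), invisibly written
#'   to `manifest.csv` as well.
#' @export
write_outputs <- function(result, out_dir,
                          formats = c("csv", "vtk", "png"), mesh = NULL) {
  stopifnot(inherits(result, "bone_remodeling"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (is.null(mesh)) mesh <- result$mesh
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(out_dir, ".failed")
  if (file.exists(failed)) unlink(failed)
  written <- character(0)

  tryCatch({
    if ("csv" %in% formats) {
      p <- file.path(out_dir, "trajectory.csv")
      readr::write_csv(result$trajectory, p)
      written <- c(written, p)
    }
    if ("vtk" %in% formats) {
      p <- file.path(out_dir, "mesh.vtk")
      write_vtk(mesh, p,
                cell_data = list(
                  region_id = match(mesh$elements$region, region_labels())),
                title = "boneadapt mesh")
      written <- c(written, p)
      for (nm in names(result$snapshots)) {
        sn <- result$snapshots[[nm]]
        p <- file.path(out_dir, paste0("snapshot_", nm, ".vtk"))
        write_vtk(mesh, p,
                  cell_data = list(
                    density = expand_trabecular(mesh, sn$density),
                    stimulus = expand_trabecular(mesh, sn$stimulus)),
                  title = paste("boneadapt", nm))
        written <- c(written, p)
      }
    }
    if ("png" %in% formats) {
      for (nm in names(result$snapshots)) {
        sn <- result$snapshots[[nm]]
        p <- file.path(out_dir, paste0("density_", nm, ".png"))
        gg <- plot_density_field(mesh, sn$density,
                                 rho_min = result$params$rho_min,
                                 rho_max = result$params$rho_max,
                                 title = nm)
        ggplot2::ggsave(p, gg, width = 6, height = 6, dpi = 120,
                        device = grDevices::png)
        written <- c(written, p)
      }
    }
    logp <- file.path(out_dir, "run.log")
    writeLines(c(
      sprintf("boneadapt run: %s after %d iterations",
              result$termination$reason, result$termination$iterations),
      sprintf("trabecular elements: %d", length(result$final_density)),
      sprintf("final mean density: %.6f g/cm^3",
              utils::tail(result$trajectory$mean_density, 1))), logp)
    written <- c(written, logp)
    cfg <- attr(result, "config")
    if (!is.null(cfg)) {
      p <- file.path(out_dir, "config.yaml")
      yaml::write_yaml(unclass(cfg), p)
      written <- c(written, p)
    }
  }, error = function(e) {
    file.create(failed)
    stop("output writing failed (marker left at ", failed, "): ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- tibble::tibble(
    file = basename(written),
    bytes = file.size(written),
    md5 = unname(tools::md5sum(written)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
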