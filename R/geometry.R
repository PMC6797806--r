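#' Parametric geometry of a 2D tooth-mandible cross section
#'
#' Parameters of the stylized distal-mesial (panoramic) section: one or
#' three anterior teeth (canine, lateral incisor, central incisor), each
#' with an elliptical enamel-capped crown, a tapered root wrapped in
#' cementum and periodontal ligament (PDL), a gingival band, a cortical
#' shell along the mandible bottom, and trabecular fill elsewhere.
#'
#' All lengths are millimetres. The defaults are sized so that meshing at
#' `element_size = 0.15` produces roughly 29,000 elements of which roughly
#' a third are trabecular, the scale of full anterior-mandible section
#' models; the coarser default `element_size = 0.6` keeps interactive runs
#' fast.
#'
#' @param n_teeth 1 or 3 teeth.
#' @param domain_width,domain_height Rectangular domain size, mm. Defaults:
#'   8 mm of width per tooth (24 x 30 for three teeth, 10 x 30 for one).
#' @param crown_height Height of the crown above the gingiva, mm.
#' @param crown_half_width Crown semi-axis at its base, mm.
#' @param root_length Root length from the crown base (gingiva top) to the
#'   apex, mm.
#' @param root_half_width Root core half-width at the crown base, mm.
#' @param root_taper Fraction of `root_half_width` remaining at the apex.
#' @param pdl_thickness Periodontal ligament thickness, mm.
#' @param cementum_thickness Cementum layer thickness, mm.
#' @param gingiva_thickness Gingival band thickness, mm.
#' @param cortical_bottom_thickness Cortical shell thickness at the bottom
#'   of the mandible, mm (default 2).
#' @param element_size Target quad edge length for meshing, mm.
#'
#' @return A list of class `"geometry_params"` with the validated fields
#'   plus derived vertical levels (`y_bone_top`, `y_crown_base`,
#'   `y_root_tip`) and tooth center abscissae `tooth_centers`.
#' @examples
#' geometry_params()
#' geometry_params(n_teeth = 1)
#' @export
geometry_params <- function(n_teeth = 3,
                            domain_width = NULL,
                            domain_height = 30,
                            crown_height = 8,
                            crown_half_width = 3.5,
                            root_length = 16,
                            root_half_width = 2.6,
                            root_taper = 0.45,
                            pdl_thickness = 0.3,
                            cementum_thickness = 0.25,
                            gingiva_thickness = 2,
                            cortical_bottom_thickness = 2,
                            element_size = 0.6) {
  if (!n_teeth %in% c(1L, 3L)) {
    stop("`n_teeth` must be 1 or 3", call. = FALSE)
  }
  n_teeth <- as.integer(n_teeth)
  if (is.null(domain_width)) {
    domain_width <- if (n_teeth == 3L) 24 else 10
  }
  lens <- c(domain_width = domain_width, domain_height = domain_height,
            crown_height = crown_height, crown_half_width = crown_half_width,
            root_length = root_length, root_half_width = root_half_width,
            pdl_thickness = pdl_thickness,
            cementum_thickness = cementum_thickness,
            gingiva_thickness = gingiva_thickness,
            cortical_bottom_thickness = cortical_bottom_thickness,
            element_size = element_size)
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad)) {
    stop("geometry lengths must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(root_taper > 0, root_taper <= 1)

  y_bone_top <- domain_height - crown_height - gingiva_thickness
  y_crown_base <- y_bone_top + gingiva_thickness
  y_root_tip <- y_crown_base - root_length
  if (y_bone_top <= cortical_bottom_thickness) {
    stop("domain too short for the crown, gingiva and cortical layers",
         call. = FALSE)
  }
  if (y_root_tip <= cortical_bottom_thickness + pdl_thickness +
      cementum_thickness) {
    stop("`root_length` exceeds the available bone depth", call. = FALSE)
  }
  spacing <- domain_width / n_teeth
  centers <- spacing * (seq_len(n_teeth) - 0.5)

  structure(
    c(as.list(lens),
      list(n_teeth = n_teeth, root_taper = root_taper,
           y_bone_top = y_bone_top, y_crown_base = y_crown_base,
           y_root_tip = y_root_tip, tooth_centers = centers)),
    class = "geometry_params"
  )
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf("<geometry_params> %d tooth/teeth, %g x %g mm, element %g mm\n",
              x$n_teeth, x$domain_width, x$domain_height, x$element_size))
  invisible(x)
}

#' All tissue region labels
#' @return Character vector of the eight region labels.
#' @export
region_labels <- function() {
  c("enamel", "dentin", "pulp", "cementum", "pdl",
    "gingiva", "cortical", "trabecular")
}

#' Build the implicit region map
#'
#' Returns a deterministic point classifier over the rectangular domain.
#' Teeth are laterally offset lobes: an elliptical crown (enamel shell over
#' dentin over a pulp chamber) above the gingiva line and a linearly
#' tapered root (dentin with a pulp canal, wrapped by cementum and then
#' PDL) embedded in trabecular bone; a cortical strip spans the bottom.
#'
#' @param params A [geometry_params()] object.
#' @return A list of class `"tooth_geometry"` holding `params` and
#'   `classify(x, y)`, a vectorized function mapping points to region
#'   labels (`NA` outside the anatomy).
#' @examples
#' geo <- build_geometry(geometry_params())
#' geo$classify(12, 1)   # "cortical": inside the 2 mm bottom shell
#' geo$classify(12, 25)  # central incisor crown
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "geometry_params"))
  p <- params

  # crown pulp chamber: ellipse seated on the crown base
  pulp_ax <- 0.35 * p$crown_half_width
  pulp_ay <- 0.45 * p$crown_height
  # root pulp canal: fraction of the local core half-width, stops short of
  # the apex
  canal_frac <- 0.30
  canal_stop <- p$y_root_tip + 0.15 * p$root_length
  enamel_shell <- 0.18  # fraction of the normalized crown radius

  classify <- function(x, y) {
    stopifnot(length(x) == length(y))
    n <- length(x)
    out <- rep(NA_character_, n)

    for (xc in p$tooth_centers) {
      d <- abs(x - xc)
      todo <- is.na(out)

      # crown (upper half-ellipse above the crown base)
      in_crown_band <- todo & y >= p$y_crown_base &
        y <= p$y_crown_base + p$crown_height & d <= p$crown_half_width
      if (any(in_crown_band)) {
        rn <- sqrt((d[in_crown_band] / p$crown_half_width)^2 +
                   ((y[in_crown_band] - p$y_crown_base) / p$crown_height)^2)
        inside <- rn <= 1
        idx <- which(in_crown_band)[inside]
        rn <- rn[inside]
        lab <- rep("dentin", length(idx))
        lab[rn > 1 - enamel_shell] <- "enamel"
        in_pulp <- (d[idx] / pulp_ax)^2 +
          ((y[idx] - p$y_crown_base) / pulp_ay)^2 <= 1
        lab[in_pulp & lab == "dentin"] <- "pulp"
        out[idx] <- lab
      }

      # root: core half-width tapers linearly from the crown base to the
      # apex; cementum and PDL wrap the core (including under the apex) via
      # an approximate offset distance
      todo <- is.na(out)
      wrap <- p$cementum_thickness + p$pdl_thickness
      in_root_band <- todo & y < p$y_crown_base &
        y >= p$y_root_tip - wrap &
        d <= p$root_half_width + wrap
      if (any(in_root_band)) {
        idx <- which(in_root_band)
        yy <- y[idx]
        y_cl <- pmax(yy, p$y_root_tip)
        w <- p$root_half_width *
          (p$root_taper + (1 - p$root_taper) *
             (y_cl - p$y_root_tip) / p$root_length)
        dx <- pmax(0, d[idx] - w)
        dy <- pmax(0, p$y_root_tip - yy)
        dist <- sqrt(dx^2 + dy^2)
        lab <- rep(NA_character_, length(idx))
        core <- dist == 0 & yy >= p$y_root_tip
        lab[core] <- "dentin"
        canal <- core & d[idx] <= canal_frac * w & yy >= canal_stop
        lab[canal] <- "pulp"
        lab[is.na(lab) & dist <= p$cementum_thickness] <- "cementum"
        lab[is.na(lab) & dist <= wrap & yy < p$y_bone_top] <- "pdl"
        out[idx[!is.na(lab)]] <- lab[!is.na(lab)]
      }
    }

    todo <- is.na(out) & x >= 0 & x <= p$domain_width & y >= 0
    out[todo & y < p$cortical_bottom_thickness] <- "cortical"
    todo <- is.na(out) & x >= 0 & x <= p$domain_width
    out[todo & y >= p$cortical_bottom_thickness & y < p$y_bone_top] <-
      "trabecular"
    todo <- is.na(out) & x >= 0 & x <= p$domain_width
    out[todo & y >= p$y_bone_top & y < p$y_crown_base] <- "gingiva"
    out
  }

  structure(list(params = p, classify = classify), class = "tooth_geometry")
}

#' Generate the structured quadrilateral mesh
#'
#' Rasterized-region meshing: an axis-aligned structured grid of square
#' 4-node quads covers the domain, each cell is labeled by classifying its
#' centroid, and cells falling outside the anatomy (above the gingiva,
#' between the crowns) are dropped. This guarantees well-shaped,
#' positively-oriented elements and deterministic region labels.
#'
#' @param geometry A `"tooth_geometry"` from [build_geometry()].
#' @param params Optional [geometry_params()]; defaults to the parameters
#'   the geometry was built with (supply one with a different
#'   `element_size` to re-mesh the same anatomy).
#' @return A list of class `"bone_mesh"`: `nodes` (tibble `node`, `x`,
#'   `y`), `elements` (tibble `element`, `n1`..`n4` counter-clockwise,
#'   `col`, `row` grid indices, `region`), `element_size`, `params`, and an
#'   empty `node_sets` (see [tag_boundaries()]).
#' @examples
#' geo <- build_geometry(geometry_params(element_size = 1))
#' mesh <- generate_mesh(geo)
#' table(mesh$elements$region)
#' @export
generate_mesh <- function(geometry, params = NULL) {
  stopifnot(inherits(geometry, "tooth_geometry"))
  p <- if (is.null(params)) geometry$params else params
  stopifnot(inherits(p, "geometry_params"))
  h <- p$element_size
  feat <- min(p$crown_half_width, p$root_length, p$gingiva_thickness,
              p$cortical_bottom_thickness)
  if (h > feat) {
    warning("element_size ", h, " mm exceeds the smallest feature size (",
            feat, " mm); labels will be coarse", call. = FALSE)
  }
  nx <- max(1L, round(p$domain_width / h))
  ny <- max(1L, round(p$domain_height / h))
  hx <- p$domain_width / nx
  hy <- p$domain_height / ny

  cx <- (seq_len(nx) - 0.5) * hx
  cy <- (seq_len(ny) - 0.5) * hy
  grid <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  lab <- geometry$classify(cx[grid$col], cy[grid$row])
  keep <- !is.na(lab)
  grid <- grid[keep, , drop = FALSE]
  lab <- lab[keep]

  # renumber only the grid nodes actually used
  node_id_grid <- function(i, j) (j - 1L) * (nx + 1L) + i  # i in 1..nx+1
  corners <- cbind(node_id_grid(grid$col,      grid$row),
                   node_id_grid(grid$col + 1L, grid$row),
                   node_id_grid(grid$col + 1L, grid$row + 1L),
                   node_id_grid(grid$col,      grid$row + 1L))
  used <- sort(unique(as.vector(corners)))
  renum <- integer(max(used))
  renum[used] <- seq_along(used)
  gi <- ((used - 1L) %% (nx + 1L)) + 1L
  gj <- ((used - 1L) %/% (nx + 1L)) + 1L

  nodes <- tibble::tibble(node = seq_along(used),
                          x = (gi - 1L) * hx, y = (gj - 1L) * hy)
  elements <- tibble::tibble(
    element = seq_len(nrow(grid)),
    n1 = renum[corners[, 1]], n2 = renum[corners[, 2]],
    n3 = renum[corners[, 3]], n4 = renum[corners[, 4]],
    col = grid$col, row = grid$row,
    region = lab
  )
  structure(list(nodes = nodes, elements = elements,
                 element_size = h, hx = hx, hy = hy,
                 params = p, node_sets = list()),
            class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh> %d nodes, %d elements (%d trabecular), h = %g mm\n",
              nrow(x$nodes), nrow(x$elements),
              sum(x$elements$region == "trabecular"), x$element_size))
  if (length(x$node_sets)) {
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tag boundary and load node sets
#'
#' Adds named node sets to the mesh: `bottom` (all nodes at the minimum
#' y), `left_edge` / `right_edge` (nodes at the domain's minimum/maximum
#' x), and `load_nodes`, a list with one small node set per tooth at the
#' occlusal (top) surface of its crown. Chewing/biting loads are later
#' split equally over each tooth's set; a set about three nodes wide avoids
#' the mesh-dependent singularity a single-node point load would create.
#'
#' @param mesh A `"bone_mesh"` from [generate_mesh()].
#' @param params Optional [geometry_params()]; defaults to the mesh's own.
#' @param load_set_size Number of apex nodes per tooth (default 3).
#' @return The mesh with `node_sets` filled in.
#' @export
tag_boundaries <- function(mesh, params = NULL, load_set_size = 3L) {
  stopifnot(inherits(mesh, "bone_mesh"))
  p <- if (is.null(params)) mesh$params else params
  nd <- mesh$nodes
  eps <- 1e-9 * max(p$domain_width, p$domain_height)
  bottom <- nd$node[abs(nd$y - min(nd$y)) < eps]
  left_edge <- nd$node[abs(nd$x - 0) < eps]
  right_edge <- nd$node[abs(nd$x - p$domain_width) < eps]

  el <- mesh$elements
  load_nodes <- vector("list", p$n_teeth)
  for (k in seq_len(p$n_teeth)) {
    xc <- p$tooth_centers[k]
    crown <- el$region %in% c("enamel", "dentin") &
      abs((el$col - 0.5) * mesh$hx - xc) <= p$crown_half_width
    cand <- unique(c(el$n1[crown], el$n2[crown], el$n3[crown], el$n4[crown]))
    if (!length(cand)) {
      stop("no crown elements found for tooth ", k,
           "; geometry and mesh are inconsistent", call. = FALSE)
    }
    ytop <- max(nd$y[cand])
    top <- cand[nd$y[cand] > ytop - mesh$hy / 2]
    top <- top[order(abs(nd$x[top] - xc), nd$x[top])]
    load_nodes[[k]] <- sort(top[seq_len(min(load_set_size, length(top)))])
    if (!length(load_nodes[[k]])) {
      stop("empty load node set for tooth ", k, call. = FALSE)
    }
  }
  mesh$node_sets <- list(bottom = bottom, left_edge = left_edge,
                         right_edge = right_edge, load_nodes = load_nodes)
  mesh
}

#' Build geometry, mesh and boundary sets in one call
#'
#' @param params A [geometry_params()] object.
#' @return A tagged `"bone_mesh"`.
#' @examples
#' mesh <- mandible_mesh(geometry_params(element_size = 1))
#' @export
mandible_mesh <- function(params = geometry_params()) {
  tag_boundaries(generate_mesh(build_geometry(params)))
}

#' Rectangular single-material bar mesh
#'
#' Structured quad mesh of a `width` x `height` rectangle with a single
#' region label, tagged with `bottom`, `left_edge`, `right_edge` node sets
#' and one load set spanning the whole top edge. Used for verification
#' problems with known closed-form solutions (uniaxial patch tests,
#' uniform-stimulus remodeling equilibria).
#'
#' @param width,height Bar dimensions, mm.
#' @param element_size Quad edge length, mm.
#' @param region Region label for every element (default `"trabecular"`).
#' @return A tagged `"bone_mesh"`.
#' @examples
#' bar_mesh(1, 10, 1)  # single column of 10 elements
#' @export
bar_mesh <- function(width, height, element_size, region = "trabecular") {
  stopifnot(width > 0, height > 0, element_size > 0,
            region %in% region_labels())
  nx <- max(1L, round(width / element_size))
  ny <- max(1L, round(height / element_size))
  hx <- width / nx
  hy <- height / ny
  grid_n <- expand.grid(i = 0:nx, j = 0:ny)
  nodes <- tibble::tibble(node = seq_len(nrow(grid_n)),
                          x = grid_n$i * hx, y = grid_n$j * hy)
  id <- function(i, j) j * (nx + 1L) + i + 1L
  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  elements <- tibble::tibble(
    element = seq_len(nrow(g)),
    n1 = id(g$i, g$j), n2 = id(g$i + 1L, g$j),
    n3 = id(g$i + 1L, g$j + 1L), n4 = id(g$i, g$j + 1L),
    col = g$i + 1L, row = g$j + 1L,
    region = region
  )
  mesh <- structure(
    list(nodes = nodes, elements = elements,
         element_size = element_size, hx = hx, hy = hy,
         params = list(domain_width = width, domain_height = height,
                       n_teeth = 1L),
         node_sets = list()),
    class = "bone_mesh")
  mesh$node_sets <- list(
    bottom = nodes$node[nodes$y == 0],
    left_edge = nodes$node[nodes$x == 0],
    right_edge = nodes$node[abs(nodes$x - width) < 1e-12 * width],
    load_nodes = list(nodes$node[abs(nodes$y - height) < 1e-12 * height]))
  mesh
}

# 4x2 matrix of corner coordinates (CCW) for one element.
element_coords <- function(mesh, e) {
  el <- mesh$elements
  idx <- c(el$n1[e], el$n2[e], el$n3[e], el$n4[e])
  cbind(mesh$nodes$x[idx], mesh$nodes$y[idx])
}
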