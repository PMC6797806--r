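test_that("point classification places tissues where the anatomy says", {
  p <- geometry_params()
  geo <- build_geometry(p)
  # inside the 2 mm cortical shell at the mandible bottom
  expect_equal(geo$classify(p$domain_width / 2, 1), "cortical")
  expect_equal(geo$classify(0.2, 1.9), "cortical")
  # bottom third of the bone, between root tips and cortical shell
  expect_equal(geo$classify(p$domain_width / 2, 4), "trabecular")
  # gingival band away from teeth (between two crowns)
  mid <- mean(p$tooth_centers[1:2])
  expect_equal(geo$classify(mid, p$y_bone_top + 0.5 * p$gingiva_thickness),
               "gingiva")
  # crown apex region is enamel; crown core is dentin; chamber is pulp
  xc <- p$tooth_centers[2]
  expect_equal(geo$classify(xc, p$y_crown_base + p$crown_height - 0.2),
               "enamel")
  expect_equal(geo$classify(xc + 0.6 * p$crown_half_width,
                            p$y_crown_base + 0.5), "dentin")
  expect_equal(geo$classify(xc, p$y_crown_base + 0.5), "pulp")
  # outside the anatomy (above the gingiva, between crowns)
  expect_true(is.na(geo$classify(mid, p$domain_height - 1)))
})

test_that("unsupported tooth counts and too-long roots are rejected", {
  expect_error(geometry_params(n_teeth = 2), "1 or 3")
  expect_error(geometry_params(root_length = 25), "available bone depth")
  expect_error(geometry_params(element_size = -0.1), "positive")
})

test_that("full-resolution mesh matches the ~29k/~9k element budget", {
  mesh <- generate_mesh(build_geometry(geometry_params(element_size = 0.15)))
  n_total <- nrow(mesh$elements)
  n_trab <- sum(mesh$elements$region == "trabecular")
  expect_gt(n_total, 29000 * 0.85)
  expect_lt(n_total, 29000 * 1.15)
  expect_gt(n_trab, 9000 * 0.8)
  expect_lt(n_trab, 9000 * 1.2)
})

test_that("element counts scale with the inverse square of element size", {
  geo <- build_geometry(geometry_params())
  n1 <- nrow(generate_mesh(geo, geometry_params(element_size = 0.3))$elements)
  n2 <- nrow(generate_mesh(geo, geometry_params(element_size = 0.6))$elements)
  expect_equal(n1 / n2, 4, tolerance = 0.1)
})

test_that("all elements are positively oriented axis-aligned quads", {
  mesh <- small_mesh()
  el <- mesh$elements
  x <- mesh$nodes$x
  y <- mesh$nodes$y
  # shoelace area of each CCW quad
  area <- 0.5 * (
    (x[el$n1] * y[el$n2] - x[el$n2] * y[el$n1]) +
    (x[el$n2] * y[el$n3] - x[el$n3] * y[el$n2]) +
    (x[el$n3] * y[el$n4] - x[el$n4] * y[el$n3]) +
    (x[el$n4] * y[el$n1] - x[el$n1] * y[el$n4]))
  expect_true(all(area > 0))
  expect_equal(area, rep(mesh$hx * mesh$hy, nrow(el)), tolerance = 1e-12)
})

test_that("all eight tissue labels occur at the default resolution", {
  mesh <- mandible_mesh(geometry_params())  # default element_size
  expect_setequal(unique(mesh$elements$region), region_labels())
})

test_that("meshing is deterministic", {
  m1 <- mandible_mesh(geometry_params(element_size = 0.7))
  m2 <- mandible_mesh(geometry_params(element_size = 0.7))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$node_sets, m2$node_sets)
})

test_that("region shares are stable under mesh refinement", {
  geo <- build_geometry(geometry_params())
  frac <- function(h) {
    m <- generate_mesh(geo, geometry_params(element_size = h))
    table(factor(m$elements$region, region_labels())) / nrow(m$elements)
  }
  d <- abs(frac(0.3) - frac(0.6))
  expect_true(all(d < 0.05))  # < 5 percentage points per region
})

test_that("trabecular elements form one connected component", {
  mesh <- small_mesh()
  el <- mesh$elements[mesh$elements$region == "trabecular", ]
  key <- paste(el$col, el$row)
  idx <- stats::setNames(seq_len(nrow(el)), key)
  visited <- rep(FALSE, nrow(el))
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- stats::na.omit(idx[paste(c(el$col[i] + 1L, el$col[i] - 1L,
                                     el$col[i], el$col[i]),
                                   c(el$row[i], el$row[i],
                                     el$row[i] + 1L, el$row[i] - 1L))])
    new <- nb[!visited[nb]]
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  expect_true(all(visited))
})

test_that("boundary and load node sets are tagged correctly", {
  mesh <- small_mesh()
  ns <- mesh$node_sets
  expect_true(all(mesh$nodes$y[ns$bottom] == min(mesh$nodes$y)))
  expect_true(all(mesh$nodes$x[ns$left_edge] == 0))
  expect_true(all(mesh$nodes$x[ns$right_edge] == mesh$params$domain_width))
  expect_length(ns$load_nodes, 3)
  expect_true(all(lengths(ns$load_nodes) >= 1))
  # load nodes sit at each tooth's occlusal surface, near the crown apex
  p <- mesh$params
  for (k in 1:3) {
    xs <- mesh$nodes$x[ns$load_nodes[[k]]]
    expect_true(all(abs(xs - p$tooth_centers[k]) < p$crown_half_width))
  }
  m1 <- mandible_mesh(geometry_params(n_teeth = 1, element_size = 0.8))
  expect_length(m1$node_sets$load_nodes, 1)
})

test_that("oversized elements trigger a warning, not an error", {
  expect_warning(mandible_mesh(geometry_params(element_size = 2.5)),
                 "smallest feature")
})

test_that("bar_mesh builds a tagged single-region grid", {
  bar <- bar_mesh(2, 6, 1)
  expect_s3_class(bar, "bone_mesh")
  expect_equal(nrow(bar$elements), 12)
  expect_true(all(bar$elements$region == "trabecular"))
  expect_length(bar$node_sets$load_nodes[[1]], 3)
})
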