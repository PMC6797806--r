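unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

test_that("element stiffness has rigid-body nullspace and linear E scaling", {
  ke <- element_stiffness(unit_square, E = 1000, nu = 0.3)
  expect_equal(ke, t(ke))
  # x-translation mode produces zero force
  tx <- rep(c(1, 0), 4)
  expect_equal(as.numeric(ke %*% tx), rep(0, 8), tolerance = 1e-9)
  # exactly three zero-energy modes
  ev <- eigen(ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 3)
  expect_true(all(ev > -1e-8 * max(ev)))
  # stiffness is linear in E
  expect_equal(element_stiffness(unit_square, 10000, 0.3), 10 * ke,
               tolerance = 1e-12)
})

test_that("inverted elements are rejected", {
  bad <- unit_square[c(1, 4, 3, 2), ]  # clockwise
  expect_error(element_stiffness(bad, 1000, 0.3), "Jacobian")
})

test_that("zero load gives a zero field and doubling loads quadruples energy", {
  mesh <- small_mesh()
  trab <- sum(mesh$elements$region == "trabecular")
  rho <- rep(0.8, trab)
  s0 <- assemble_and_solve(mesh, density = rho,
                           load = load_case(vertical = 0, lateral = 0))
  expect_true(all(s0$displacements$ux == 0))
  expect_true(all(s0$elements$U == 0))
  s1 <- assemble_and_solve(mesh, density = rho, load = load_case())
  s2 <- assemble_and_solve(mesh, density = rho,
                           load = load_case(vertical = -200, lateral = 20))
  expect_equal(s2$total_energy, 4 * s1$total_energy, tolerance = 1e-10)
})

test_that("uniaxial patch is uniform and matches sigma^2/(2E)", {
  bar <- uniaxial_bar(width = 3, height = 5, element_size = 0.5)
  sigma <- -10
  ld <- load_case(bc_mode = "free", thickness = 1)
  sol <- assemble_and_solve(
    bar, nu0_materials(), rep(1.0, nrow(bar$elements)), ld,
    nodal_forces = consistent_top_traction(bar, sigma, ld$thickness))
  U <- strain_energy_density(sol, bar)
  expect_equal(U, rep(sigma^2 / (2 * 3790), length(U)), tolerance = 1e-6)
  expect_equal(sol$elements$syy, rep(sigma, length(U)), tolerance = 1e-6)
})

test_that("total element energy equals the external work", {
  mesh <- small_mesh()
  rho <- rep(0.8, sum(mesh$elements$region == "trabecular"))
  ld <- load_case()
  sol <- assemble_and_solve(mesh, density = rho, load = ld)
  V <- mesh$hx * mesh$hy * ld$thickness
  expect_equal(sum(sol$elements$U * V), sol$total_energy,
               tolerance = 1e-8 * sol$total_energy)
  # reactions balance the applied loads: 3 teeth x (10, -100) N
  expect_equal(unname(sol$reaction["fy"]), 300, tolerance = 1e-8)
})

test_that("rigid-body motion leaves element energy unchanged", {
  ke <- element_stiffness(unit_square, 1000, 0.25)
  u <- rnorm(8)
  rigid <- 0.3 * rep(c(1, 0), 4) - 0.7 * rep(c(0, 1), 4)
  e1 <- as.numeric(t(u) %*% ke %*% u)
  e2 <- as.numeric(t(u + rigid) %*% ke %*% (u + rigid))
  expect_equal(e1, e2, tolerance = 1e-9 * e1)
})

test_that("homogeneous patch energy is refinement-independent", {
  ld <- load_case(bc_mode = "free", thickness = 1)
  energy <- function(h) {
    bar <- uniaxial_bar(width = 2, height = 4, element_size = h)
    sol <- assemble_and_solve(
      bar, nu0_materials(), rep(1.0, nrow(bar$elements)), ld,
      nodal_forces = consistent_top_traction(bar, -8, ld$thickness))
    sol$total_energy
  }
  expect_equal(energy(1), energy(0.5), tolerance = 1e-3)
})

test_that("boundary-condition modes constrain the side edges as specified", {
  mesh <- small_mesh()
  rho <- rep(0.8, sum(mesh$elements$region == "trabecular"))
  edges <- c(mesh$node_sets$left_edge, mesh$node_sets$right_edge)
  solc <- assemble_and_solve(mesh, density = rho,
                             load = load_case(bc_mode = "constrained"))
  solf <- assemble_and_solve(mesh, density = rho,
                             load = load_case(bc_mode = "free"))
  expect_true(all(solc$displacements$ux[edges] == 0))
  expect_gt(max(abs(solf$displacements$ux[edges])), 0)
  # bottom is fully fixed in both modes
  expect_true(all(solc$displacements$uy[mesh$node_sets$bottom] == 0))
  expect_true(all(solf$displacements$uy[mesh$node_sets$bottom] == 0))
})

test_that("a mesh without a bottom set is reported as singular", {
  bar <- uniaxial_bar()
  bar$node_sets$bottom <- integer(0)
  expect_error(
    assemble_and_solve(bar, density = rep(0.8, nrow(bar$elements)),
                       load = load_case(bc_mode = "free")),
    "bottom node set")
})
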