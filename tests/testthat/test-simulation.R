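test_that("convergence check needs two consecutive sub-tolerance steps", {
  expect_true(convergence_check(c(1.000, 1.0002, 1.0003), 0.0003))
  expect_false(convergence_check(c(1.0, 1.1, 1.1001), 0.0003))
  expect_true(convergence_check(rep(1.5, 5), 0.0003))
  expect_false(convergence_check(c(1.0, 1.0), 0.0003))  # too short
  expect_false(convergence_check(c(1.0, 1.0005, 1.0006), 0.0003))
})

test_that("checkerboard index is 0 for uniform and 1 for alternation", {
  bar <- bar_mesh(4, 4, 1)
  expect_equal(checkerboard_index(bar, rep(0.8, 16)), 0)
  parity <- (bar$elements$col + bar$elements$row) %% 2
  alt <- ifelse(parity == 0, 0.1, 2.2)
  expect_equal(checkerboard_index(bar, alt), 1)
  single <- bar_mesh(1, 1, 1)
  expect_error(checkerboard_index(single, 0.8), "adjacent")
  expect_error(checkerboard_index(bar, rep(0.8, 3)), "one value per")
})

test_that("a stationary start terminates after two iterations unchanged", {
  bar <- uniaxial_bar()
  # S(0.8) = 25 / (2 * 3790 * 0.8^4) = 0.00805 J/g, inside the default zone
  res <- run_simulation(bar, nu0_materials(),
                        load_case(vertical = -5, lateral = 0, thickness = 1),
                        initial_density = 0.8)
  expect_equal(res$termination$reason, "converged")
  expect_equal(res$termination$iterations, 2)
  expect_equal(diff(range(res$trajectory$mean_density)), 0)
  expect_equal(res$final_density, rep(0.8, nrow(bar$elements)))
})

test_that("runs with identical config and seed are identical", {
  mesh <- small_mesh()
  r1 <- run_simulation(mesh, perturbation = 0.02, seed = 11,
                       snapshots = c(0, 5))
  r2 <- run_simulation(mesh, perturbation = 0.02, seed = 11,
                       snapshots = c(0, 5))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_density, r2$final_density)
  r3 <- run_simulation(mesh, perturbation = 0.02, seed = 12,
                       snapshots = c(0, 5))
  expect_false(identical(r1$final_density, r3$final_density))
  expect_error(run_simulation(mesh, perturbation = 0.02), "seed")
})

test_that("density clamps are never violated along a trajectory", {
  mesh <- small_mesh()
  res <- run_simulation(mesh, initial_density = 0.2)
  expect_true(all(res$trajectory$min_density >= 0.1))
  expect_true(all(res$trajectory$max_density <= 2.2))
  expect_true(all(res$final_density >= 0.1 & res$final_density <= 2.2))
})

test_that("a saturated low-density start grows by exactly 5% where S > S_u", {
  mesh <- small_mesh()
  res <- run_simulation(mesh, initial_density = 0.2, snapshots = c(0, 1))
  s0 <- res$snapshots$iter0
  s1 <- res$snapshots$iter1
  p <- res$params
  # stimuli beyond the point where the linear branch reaches the cap
  S_u <- (1 + p$delta) * p$S0 + p$saturation_fraction * 0.2 / p$BdT
  sat <- s0$stimulus > S_u
  expect_gt(mean(sat), 0.5)  # high loads: most elements saturated
  expect_equal(s1$density[sat], 1.05 * s0$density[sat], tolerance = 1e-12)
})

test_that("stimulus dispersion contracts over the early iterations", {
  res <- ref_run()
  iqr <- function(s) diff(quantile(s$stimulus, c(0.25, 0.75)))
  expect_lt(iqr(res$snapshots$iter10), iqr(res$snapshots$iter1))
})

test_that("tidiers expose the trajectory and a one-row summary", {
  bar <- uniaxial_bar()
  res <- run_simulation(bar, nu0_materials(),
                        load_case(vertical = -5, lateral = 0, thickness = 1),
                        initial_density = 0.3)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "mean_density", "min_density",
                     "max_density", "eq_zone_fraction", "checkerboard"))
  expect_equal(nrow(td), res$termination$iterations + 1)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(g$converged)
  expect_equal(g$mean_density, tail(td$mean_density, 1))
})
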