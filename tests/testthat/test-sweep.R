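test_that("a singleton sweep reproduces a plain simulation exactly", {
  mesh <- small_mesh()
  sw <- run_sweep(sweep_spec("reference_stimulus", values = 0.008,
                             mesh = mesh, snapshots = c(0)))
  plain <- run_simulation(mesh, params = remodeling_params(S0 = 0.008),
                          snapshots = c(0))
  expect_identical(sw$results[[1]]$trajectory, plain$trajectory)
  expect_identical(sw$results[[1]]$final_density, plain$final_density)
  expect_equal(nrow(sw$summary), 1)
})

test_that("unknown sweep parameters are rejected", {
  expect_error(sweep_spec("load_magnitude", mesh = small_mesh()))
})

test_that("default sweep grids follow the study protocol", {
  m <- small_mesh()
  expect_equal(sweep_spec("initial_density", mesh = m)$values,
               seq(0.2, 2.0, by = 0.2))
  expect_equal(sweep_spec("reference_stimulus", mesh = m)$values,
               seq(0.002, 0.014, by = 0.002))
  expect_equal(sweep_spec("equilibrium_half_width", mesh = m)$values,
               seq(0.05, 0.45, by = 0.1))
  expect_equal(sweep_spec("initial_perturbation", mesh = m)$values,
               c(0.005, 0.01, 0.02, 0.05))
  expect_equal(sweep_spec("bc_mode", mesh = m)$values,
               c("constrained", "free"))
})

test_that("field similarity is 1 for identical and 0 for opposite-clamp fields", {
  a <- runif(50, 0.1, 2.2)
  expect_equal(field_similarity(a, a), 1)
  expect_equal(field_similarity(rep(0.1, 10), rep(2.2, 10)), 0)
  expect_error(field_similarity(a, a[-1]), "length")
  expect_error(field_similarity(a, a, mask = integer(0)), "empty mask")
  expect_error(field_similarity(a, a, mask = c(TRUE, FALSE)), "mask")
})

test_that("extreme-area fractions count the near-clamp bands", {
  expect_equal(extreme_area_fractions(rep(0.8, 10), 0.3, 2.0),
               c(low_fraction = 0, high_fraction = 0))
  expect_equal(extreme_area_fractions(rep(2.2, 7), 0.3, 2.0)[["high_fraction"]],
               1)
  f <- extreme_area_fractions(c(0.1, 0.2, 1.0, 2.1, 2.2), 0.3, 2.0)
  expect_equal(unname(f), c(0.4, 0.4))
  expect_error(extreme_area_fractions(1, 2, 1), "below")
})

test_that("masks select the peri-root band and the bottom half", {
  mesh <- small_mesh()
  el <- mesh$elements
  trab <- el$region == "trabecular"
  pr <- mask_peri_root(mesh, width = 2)
  bh <- mask_bottom_half(mesh)
  expect_length(pr, sum(trab))
  expect_true(any(pr) && !all(pr))
  expect_true(any(bh) && !all(bh))
  # every trabecular element touching a PDL element is in the band
  cx <- (el$col - 0.5) * mesh$hx
  cy <- (el$row - 0.5) * mesh$hy
  pdl_x <- cx[el$region == "pdl"]
  pdl_y <- cy[el$region == "pdl"]
  d2 <- vapply(which(trab), function(i) {
    min((cx[i] - pdl_x)^2 + (cy[i] - pdl_y)^2)
  }, numeric(1))
  expect_true(all(pr[d2 <= mesh$hx^2]))
  # bottom-half elements lie below the trabecular mid-height
  expect_true(max(cy[trab][bh]) <= min(cy[trab][!bh]) + mesh$hy)
})

test_that("perturbed initial fields converge to the unperturbed run as p -> 0", {
  mesh <- small_mesh()
  base <- run_simulation(mesh, snapshots = c(0))
  dev <- vapply(c(0.05, 0.01, 0.001), function(p) {
    r <- run_simulation(mesh, perturbation = p, seed = 7, snapshots = c(0))
    mean(abs(r$final_density - base$final_density))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))   # shrinks with p
  expect_lt(dev[3], 0.005)          # and vanishes in the limit
})

test_that("sweep summaries are one row per value with recorded thresholds", {
  mesh <- small_mesh()
  sw <- run_sweep(sweep_spec("bc_mode", mesh = mesh, snapshots = c(0)),
                  low_threshold = 0.25, high_threshold = 2.1)
  expect_equal(nrow(sw$summary), 2)
  expect_equal(sw$summary$low_threshold, rep(0.25, 2))
  expect_equal(sw$summary$value, c("constrained", "free"))
  expect_identical(tidy(sw), sw$summary)
})
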