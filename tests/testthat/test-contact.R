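# Contact simulator: passage outcomes, scaling properties and the
# bisection search.  Unit tests run at a deliberately coarse mesh
# (resolution 4) to stay fast; the quantitative scaling checks live in the
# acceptance suite at the default resolution.

test_that("an unloaded cell larger than the gap stays put", {
  tc <- trapped_case()
  o <- simulate_passage(tc$mesh, tc$material, tc$surface,
                        parabolic_load(0, 6), control = fast_control())
  expect_false(o$escaped)
  expect_true(o$converged)
  expect_lt(max(abs(diff(o$centroid_path$centroid_x_um))), 1e-8)
})

test_that("a cell smaller than the gap passes at any positive pressure", {
  m <- cell_mesh(7, 4)
  o <- simulate_passage(m, material_nh(430),
                        build_pillar_surface(trap_geometry(8)),
                        parabolic_load(5, 3.5), control = fast_control())
  expect_true(o$escaped)
})

test_that("a moderately loaded large cell reaches a trapped equilibrium", {
  o <- trapped_case()$outcome
  expect_false(o$escaped)
  expect_true(o$converged)
  # centroid advances monotonically under the monotone load ramp (tiny
  # nanometre-scale settling adjustments are within solver tolerance)
  expect_true(all(diff(o$centroid_path$centroid_x_um) > -0.01))
  # contact penetration stays within the configured tolerance
  expect_lt(o$max_penetration_um, o$penetration_tol_um)
  # no element inversion in accepted states
  expect_gt(o$min_j, 0)
  expect_gt(o$max_principal_stretch, 1)
})

test_that("jointly rescaling load and modulus leaves the outcome unchanged", {
  tc <- trapped_case()
  o1 <- tc$outcome
  o2 <- simulate_passage(tc$mesh, material_nh(860), tc$surface,
                         parabolic_load(60, 6), control = fast_control())
  expect_equal(o1$escaped, o2$escaped)
  expect_lt(max(abs(o1$final_nodes - o2$final_nodes)), 1e-2)
})

test_that("initial positions inside the pillars are rejected", {
  tc <- trapped_case()
  expect_error(
    simulate_passage(tc$mesh, tc$material, tc$surface,
                     parabolic_load(10, 6), control = fast_control(),
                     position = c(0, 0, 0)),
    class = "pillartrap_error_invalid_input")
})

test_that("free passage short-circuits the critical-pressure search", {
  r <- find_critical_pressure(cell_spec(6, 430), trap_geometry(8))
  expect_equal(r$pc_pa, 0)
  expect_equal(r$iterations, 0L)
})

test_that("bisection returns a consistent bracket and is deterministic", {
  r1 <- find_critical_pressure(cell_spec(10, 430), trap_geometry(8),
                               control = fast_control())
  r2 <- find_critical_pressure(cell_spec(10, 430), trap_geometry(8),
                               control = fast_control())
  expect_identical(r1$pc_pa, r2$pc_pa)
  expect_lt(r1$bracket[1], r1$pc_pa)
  expect_equal(r1$pc_pa, r1$bracket[2])
  expect_lte(diff(r1$bracket), 0.05 * r1$bracket[2] + 1e-12)
  expect_gt(r1$pc_pa, 0)
})

test_that("sweeps record free passage, exclusions and stay reproducible", {
  sw <- sweep_critical_pressure(6, 430, 8, control = fast_control())
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$pc_pa, 0)
  # combinations beyond the validated squeeze envelope are flagged failed
  expect_warning(
    sw2 <- sweep_critical_pressure(c(6, 30), 430, 5,
                                   control = fast_control()),
    class = "pillartrap_warning_sweep_failures")
  expect_true(all(sw2$failed[sw2$diameter_um == 30]))
  sw3 <- sweep_critical_pressure(c(6, 10), 430, 8, control = fast_control())
  sw4 <- sweep_critical_pressure(c(6, 10), 430, 8, control = fast_control())
  expect_identical(sw3$pc_pa, sw4$pc_pa)
})
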