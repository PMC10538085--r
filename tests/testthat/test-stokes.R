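# Carrier-flow solver: verification against closed forms and the
# Stokes-regime linearity of the trapping-unit flow.

test_that("zero flow rate gives identically zero fields", {
  dom <- flow_domain(trap_geometry(6), refine_um = 1.2)
  s <- suppressMessages(solve_flow(dom, flow_conditions(0)))
  expect_lt(max(abs(s$u)), 1e-10)
  expect_lt(max(abs(s$v)), 1e-10)
  expect_lt(max(abs(s$p)), 1e-10)
})

test_that("straight-channel pressure gradient matches plane Poiseuille", {
  dom <- flow_domain(trap_geometry(6), pillars = FALSE, width_um = 60,
                     length_um = 200)
  s <- suppressMessages(solve_flow(dom, flow_conditions(5),
                                   depth_term = FALSE,
                                   inlet_profile = "parabolic"))
  pr <- pressure_along_gap(
    s, tibble::tibble(x = seq(-60, 60, length.out = 50), y = 0))
  dpdx <- coef(lm(pressure_pa ~ arc_length_um, data = pr))[[2]]
  q2d <- 5e9 / 60 / 50                      # per-depth flow rate, um^2/s
  dpdx_theory <- -12 * 1e-3 * q2d / 60^3
  expect_lt(abs(dpdx - dpdx_theory) / abs(dpdx_theory), 0.05)
})

test_that("inlet and outlet fluxes balance to solver precision", {
  dom <- flow_domain(trap_geometry(6))
  s <- suppressMessages(solve_flow(dom, flow_conditions(10)))
  expect_lt(abs(s$flux_in_um3_s - s$flux_out_um3_s) /
              abs(s$flux_in_um3_s), 1e-3)
  # and the inlet flux equals the requested flow rate
  expect_lt(abs(s$flux_in_um3_s - 10e9 / 60) / (10e9 / 60), 0.02)
})

test_that("gap pressure drop is proportional to the flow rate", {
  dom <- flow_domain(trap_geometry(6))
  drops <- vapply(c(1, 5, 10), function(q) {
    gap_mean_pressure(suppressMessages(solve_flow(dom, flow_conditions(q))))
  }, numeric(1))
  expect_gt(drops[1], 0)
  expect_lt(abs(drops[2] / drops[1] - 5) / 5, 0.02)
  expect_lt(abs(drops[3] / drops[1] - 10) / 10, 0.02)
  # intercept of the three-point line is zero relative to the drops
  fit <- lm(drops ~ c(1, 5, 10))
  expect_lt(abs(coef(fit)[[1]]) / drops[3], 0.02)
})

test_that("gap pressure profiles at increasing flow rates nest in order", {
  dom <- flow_domain(trap_geometry(6))
  profs <- lapply(c(1, 5, 10), function(q) {
    s <- suppressMessages(solve_flow(dom, flow_conditions(q)))
    pressure_along_gap(s, smooth_um = 8)$pressure_pa
  })
  # upstream pressure level ordered by flow rate
  expect_true(all(profs[[1]][1:50] < profs[[2]][1:50]))
  expect_true(all(profs[[2]][1:50] < profs[[3]][1:50]))
  # proportionality along the whole profile (Stokes linearity)
  expect_lt(max(abs(profs[[3]] - 10 * profs[[1]])) /
              max(abs(profs[[3]])), 0.02)
})

test_that("the smoothed centreline profile is close to monotone through the gap", {
  dom <- flow_domain(trap_geometry(6))
  s <- suppressMessages(solve_flow(dom, flow_conditions(10)))
  pr <- pressure_along_gap(s, smooth_um = 12)
  drop <- pr$pressure_pa[1] - dplyr::last(pr$pressure_pa)
  expect_gt(drop, 0)
  # residual mesh-scale noise stays under a few percent of the total drop
  expect_lt(max(diff(pr$pressure_pa)), 0.1 * drop)
})

test_that("cross-gap velocity is symmetric, no-slip at the edges and near-parabolic", {
  dom <- flow_domain(trap_geometry(6))
  s <- suppressMessages(solve_flow(dom, flow_conditions(10)))
  vp <- gap_velocity_profile(s, 21)
  expect_equal(vp$u_um_s[1], 0)
  expect_equal(vp$u_um_s[21], 0)
  expect_gt(min(vp$u_um_s[8:14]), 0)
  r2 <- summary(lm(u_um_s ~ y_um + I(y_um^2), data = vp))$r.squared
  # the sharp-edged throat yields a slightly flat-topped (orifice-like)
  # profile; the parabola still explains the bulk of the variation
  expect_gt(r2, 0.9)
})

test_that("flow solution exposes tidy fields and a plot", {
  dom <- flow_domain(trap_geometry(6), refine_um = 1.2)
  s <- suppressMessages(solve_flow(dom, flow_conditions(1)))
  df <- tibble::as_tibble(s)
  expect_named(df, c("x", "y", "u_um_s", "v_um_s", "p_pa"))
  expect_equal(nrow(df), nrow(dom$nodes))
  expect_s3_class(autoplot(s), "ggplot")
  expect_error(pressure_along_gap(s, tibble::tibble(x = 1e5, y = 0)),
               class = "pillartrap_error_invalid_input")
})
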