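# The parabolic load: profile factor, tractions and resultant.

test_that("profile factor is parabolic, clamped and bounded", {
  l <- parabolic_load(50, 10)
  expect_equal(field_factor(l, 0, 0), 1)
  expect_equal(field_factor(l, 6, 8), 0)          # rim of the disk
  expect_equal(field_factor(l, 5, 0), 0.75)
  expect_equal(field_factor(l, 30, 0), 0)         # clamped outside
  yz <- matrix(runif(200, -15, 15), ncol = 2)
  f <- field_factor(l, yz[, 1], yz[, 2])
  expect_true(all(f >= 0 & f <= 1))
})

test_that("the load resultant has the closed form P0 pi r^2 / 2", {
  for (case in list(c(50, 8.5), c(1, 2), c(300, 15))) {
    l <- parabolic_load(case[1], case[2])
    # independent oracle: 2D quadrature of the profile over the disk
    quad <- stats::integrate(function(rho) {
      case[1] * (1 - rho^2 / case[2]^2) * 2 * pi * rho
    }, 0, case[2], rel.tol = 1e-10)$value
    expect_lt(abs(load_resultant(l) - quad) / quad, 1e-6)
  }
})

test_that("tractions act along +x on the front region only and are axisymmetric", {
  l <- parabolic_load(10, 2)
  pts <- tibble::tibble(x = c(-1, -0.5, 1), y = c(0, 1, 0), z = 0)
  tr <- apply_traction(l, pts, centroid = c(0, 0, 0))
  expect_true(all(tr$t_x[pts$x <= 0] >= 0))
  expect_equal(tr$t_x[3], 0)                      # downstream: unloaded
  expect_equal(tr$t_y, rep(0, 3))
  # zero magnitude, zero traction
  tr0 <- apply_traction(parabolic_load(0, 2), pts, centroid = c(0, 0, 0))
  expect_equal(tr0$t_x, rep(0, 3))
  # rotation about the flow axis leaves tractions unchanged
  th <- 1.1
  rot <- tibble::tibble(x = pts$x,
                        y = pts$y * cos(th) - pts$z * sin(th),
                        z = pts$y * sin(th) + pts$z * cos(th))
  expect_equal(apply_traction(l, rot, centroid = c(0, 0, 0))$t_x, tr$t_x)
  # empty front region warns and loads nothing
  behind <- tibble::tibble(x = c(1, 2), y = 0, z = 0)
  expect_warning(tr2 <- apply_traction(l, behind, centroid = c(0, 0, 0)),
                 class = "pillartrap_warning_empty_selection")
  expect_equal(tr2$t_x, c(0, 0))
})

test_that("load construction validates its inputs", {
  expect_error(parabolic_load(-1, 5),
               class = "pillartrap_error_invalid_input")
  expect_error(parabolic_load(10, 0),
               class = "pillartrap_error_invalid_input")
})
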