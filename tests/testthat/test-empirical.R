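# Closed-form prediction, power-law regression, model-order comparison and
# validation statistics.

test_that("predicted critical pressure matches the closed form and its units", {
  cell <- cell_spec(17, 430)
  expect_equal(predict_critical_pressure(cell, trap_geometry(8)),
               0.027 * 430 * (17 / 8)^2)
  expect_equal(round(predict_critical_pressure(cell, trap_geometry(8)), 2),
               52.43)
  # ratio one: prefactor times modulus
  expect_equal(predict_critical_pressure(cell_spec(8, 500), 8), 0.027 * 500)
  # ratio two at unit modulus
  expect_equal(predict_critical_pressure(cell_spec(10, 1), 5), 0.108)
})

test_that("prediction is linear in modulus and depends only on the size ratio", {
  gaps <- c(4, 6.5, 9)
  for (g in gaps) {
    for (E in c(130, 430, 650)) {
      p1 <- predict_critical_pressure(cell_spec(15, E), g)
      p2 <- predict_critical_pressure(cell_spec(15, 2 * E), g)
      expect_equal(p2, 2 * p1)
    }
    for (lam in c(0.5, 2, 3.7)) {
      p1 <- predict_critical_pressure(cell_spec(15, 430), g)
      p2 <- predict_critical_pressure(cell_spec(15 * lam, 430), g * lam)
      expect_equal(p2, p1)
    }
  }
})

test_that("invalid cells, gaps and models are rejected", {
  expect_error(cell_spec(-1, 430), class = "pillartrap_error_invalid_input")
  expect_error(cell_spec(17, 430, poisson_ratio = 0.5),
               class = "pillartrap_error_invalid_input")
  expect_error(predict_critical_pressure(cell_spec(17, 430), -2),
               class = "pillartrap_error_invalid_input")
  expect_error(trap_geometry(80), class = "pillartrap_error_invalid_geometry")
  expect_error(power_law_model(exponent = 0),
               class = "pillartrap_error_invalid_input")
})

test_that("add_critical_pressure appends predictions to tables", {
  df <- tibble::tibble(diameter_um = c(17, 20), E_pa = c(430, 360),
                       gap_um = 8)
  out <- add_critical_pressure(df)
  expect_equal(out$pc_pa, 0.027 * df$E_pa * (df$diameter_um / 8)^2)
  expect_error(add_critical_pressure(dplyr::select(df, -gap_um)),
               class = "pillartrap_error_invalid_input")
})

test_that("fitting noiseless power-law data recovers the generating model", {
  grid <- eq4_grid()
  for (method in c("log", "nls")) {
    fit <- fit_power_law(grid, method = method)
    expect_lt(abs(fit$model$coefficient - 0.027) / 0.027, 1e-8)
    expect_lt(abs(fit$model$exponent - 2) / 2, 1e-8)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
  # fixed-exponent fit at the generating order is exact too
  fit2 <- fit_power_law(grid, exponent = 2)
  expect_lt(abs(fit2$model$coefficient - 0.027) / 0.027, 1e-10)
})

test_that("noisy fits recover the coefficient within Monte-Carlo tolerance", {
  # multiplicative lognormal noise, sigma = 0.1, n = 200: the standard
  # error of the fitted log-coefficient is ~0.1/sqrt(200) < 1%, so a 5%
  # band is a > 5-sigma check
  set.seed(101)
  base <- eq4_grid()
  rows <- base[sample.int(nrow(base), 200, replace = TRUE), ]
  rows$pc_pa <- rows$pc_pa * exp(rnorm(200, 0, 0.1))
  fit <- fit_power_law(rows)
  expect_lt(abs(fit$model$coefficient - 0.027) / 0.027, 0.05)
  expect_lt(abs(fit$model$exponent - 2), 0.1)
})

test_that("degenerate regression designs raise classed errors", {
  grid <- eq4_grid()
  expect_error(fit_power_law(grid[1:2, ]),
               class = "pillartrap_error_insufficient_data")
  one_ratio <- dplyr::filter(grid, diameter_um == 20, gap_um == 8)
  expect_error(fit_power_law(one_ratio, exponent = "free"),
               class = "pillartrap_error_unidentifiable_model")
  # the same design is fine when the exponent is fixed
  expect_s3_class(fit_power_law(one_ratio, exponent = 2), "pc_fit")
  zero <- dplyr::mutate(grid[1:5, ], pc_pa = c(0, pc_pa[2:5]))
  expect_warning(fit_power_law(zero, exponent = 2),
                 class = "pillartrap_warning_dropped_records")
})

test_that("model-order comparison ranks the generating order first", {
  grid <- eq4_grid()
  # the mismatched fixed orders can fit worse than a constant on the
  # pressure scale; that warning is expected here
  tab <- suppressWarnings(compare_model_orders(grid))
  expect_equal(tab$exponent[1], 2)
  expect_gt(tab$r_squared[1], 1 - 1e-10)
  expect_true(all(tab$r_squared <= 1 + 1e-12))
  expect_equal(tab$rank, 1:3)
  expect_error(compare_model_orders(grid[1:2, ]),
               class = "pillartrap_error_insufficient_data")
})

test_that("validation statistics behave as correlation and R-squared should", {
  cell <- cell_spec(15, 300)
  gaps <- c(5, 6, 7, 9)
  obs <- tibble::tibble(
    gap_um = gaps,
    pc_pa = vapply(gaps, function(g)
      predict_critical_pressure(cell, g), numeric(1)))
  self <- validate_against(power_law_model(), cell, obs)
  expect_equal(self$r_squared, 1)
  expect_equal(self$pearson_r, 1)
  # a constant offset keeps r = 1 but lowers R-squared about the identity
  shifted <- dplyr::mutate(obs, pc_pa = pc_pa + 5)
  sh <- validate_against(power_law_model(), cell, shifted)
  expect_equal(sh$pearson_r, 1)
  expect_lt(sh$r_squared, 1)
  const <- tibble::tibble(gap_um = c(6, 6, 6), pc_pa = c(3, 3, 3))
  expect_error(validate_against(power_law_model(), cell, const),
               class = "pillartrap_error_undefined_correlation")
  expect_error(validate_against(power_law_model(), cell, obs[1:2, ]),
               class = "pillartrap_error_insufficient_data")
})

test_that("tidy, glance, augment and autoplot summarise fits coherently", {
  fit <- fit_power_law(eq4_grid())
  td <- tidy(fit)
  expect_equal(td$term, c("coefficient", "exponent"))
  gl <- glance(fit)
  expect_equal(gl$n_points, nrow(eq4_grid()))
  au <- augment(fit)
  expect_equal(au$pc_pa - au$.resid, au$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
})
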