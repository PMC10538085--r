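# Empirical critical-pressure model: closed-form prediction, power-law
# regression over sweep datasets, model-order comparison and validation
# statistics.

pc_formula <- function(coefficient, exponent, E, a, g) {
  coefficient * E * (a / g)^exponent
}

#' Predict the critical trapping pressure of a cell at a gap
#'
#' Evaluates the power-law relation `Pc = c * E * (a/g)^n` for one cell and
#' one trapping-unit geometry. The prediction is exactly linear in the cell
#' modulus and depends on diameter and gap only through their ratio.
#'
#' @param cell A [cell_spec()].
#' @param geometry A [trap_geometry()], or a single positive gap in
#'   micrometres.
#' @param model A [power_law_model()]. Default: the published calibration
#'   `0.027 * E * (a/g)^2`.
#'
#' @return Critical pressure in pascals (scalar).
#' @examples
#' predict_critical_pressure(cell_spec(17, 430), trap_geometry(8))
#' @export
predict_critical_pressure <- function(cell, geometry,
                                      model = power_law_model()) {
  if (!inherits(cell, "cell_spec")) {
    pt_abort("`cell` must be a cell_spec object.", "invalid_input")
  }
  gap <- if (inherits(geometry, "trap_geometry")) geometry$gap_um else geometry
  check_number(gap, "gap_um")
  if (!inherits(model, "power_law_model")) {
    pt_abort("`model` must be a power_law_model object.", "invalid_input")
  }
  pc_formula(model$coefficient, model$exponent,
             cell$youngs_modulus_pa, cell$diameter_um, gap)
}

#' Add critical-pressure predictions to a data frame
#'
#' Data-frame-first companion of [predict_critical_pressure()]: takes a table
#' of cells/gaps and appends a `pc_pa` column. Rows where the cell is not
#' larger than the gap still get the formula value; set them to zero yourself
#' if you are modelling free passage.
#'
#' @param data A data frame with columns `diameter_um`, `gap_um`, and either
#'   `youngs_modulus_pa` or `E_pa`.
#' @param model A [power_law_model()].
#'
#' @return `data` as a tibble with an added `pc_pa` column.
#' @examples
#' tibble::tibble(diameter_um = c(17, 20), E_pa = 430, gap_um = 8) |>
#'   add_critical_pressure()
#' @export
add_critical_pressure <- function(data, model = power_law_model()) {
  if (!is.data.frame(data)) {
    pt_abort("`data` must be a data frame.", "invalid_input")
  }
  e_col <- intersect(c("youngs_modulus_pa", "E_pa"), names(data))[1]
  if (is.na(e_col) || !all(c("diameter_um", "gap_um") %in% names(data))) {
    pt_abort(
      "`data` needs columns `diameter_um`, `gap_um` and `youngs_modulus_pa` (or `E_pa`).",
      "invalid_input")
  }
  if (any(data$diameter_um <= 0) || any(data$gap_um <= 0)) {
    pt_abort("Diameters and gaps must be strictly positive.", "invalid_input")
  }
  dplyr::mutate(as_tibble(data),
                pc_pa = pc_formula(model$coefficient, model$exponent,
                                   .data[[e_col]], .data$diameter_um,
                                   .data$gap_um))
}

normalize_records <- function(records) {
  if (!is.data.frame(records)) {
    pt_abort("`records` must be a data frame of sweep records.",
             "invalid_input")
  }
  records <- as_tibble(records)
  if ("youngs_modulus_pa" %in% names(records) && !"E_pa" %in% names(records)) {
    records <- dplyr::rename(records, E_pa = "youngs_modulus_pa")
  }
  need <- c("E_pa", "diameter_um", "gap_um", "pc_pa")
  if (!all(need %in% names(records))) {
    pt_abort(sprintf("`records` needs columns %s.",
                     paste0("`", need, "`", collapse = ", ")),
             "invalid_input")
  }
  records
}

#' Fit the power-law critical-pressure relation to sweep data
#'
#' Estimates coefficient and exponent of `Pc = c * E * (a/g)^n` from a table
#' of (modulus, diameter, gap, critical pressure) records. The model is
#' linear in `E` by construction; only `c` (and optionally `n`) are fitted.
#'
#' The default objective is ordinary least squares on `log(Pc)`, which
#' linearises the power law and weighs relative errors equally across
#' pressure decades. `method = "nls"` instead minimises untransformed squared
#' pressure residuals with [minpack.lm::nlsLM()], multi-started at exponents
#' 1, 2 and 3 and bounded to n in [0.5, 4], as a sensitivity check.
#'
#' @param records Data frame with columns `E_pa` (or `youngs_modulus_pa`),
#'   `diameter_um`, `gap_um`, `pc_pa`. Rows with `pc_pa <= 0` (free passage)
#'   carry no information about the power law and are dropped with a warning.
#' @param exponent Either `"free"` (fit `n`) or a fixed positive number.
#' @param method `"log"` (default) or `"nls"`, see Details.
#'
#' @return A `pc_fit` object with the fitted [power_law_model()], goodness of
#'   fit on the pressure scale (`r_squared`), residual standard errors on the
#'   log and pressure scales (`se_log`, `se_pa`), residuals and data. Use
#'   [tidy()] / [glance()] for tabular summaries.
#' @examples
#' grid <- tidyr::expand_grid(E_pa = c(350, 650), diameter_um = c(12, 17, 25),
#'                            gap_um = c(4, 8)) |>
#'   dplyr::mutate(pc_pa = 0.027 * E_pa * (diameter_um / gap_um)^2)
#' fit_power_law(grid)
#' @export
fit_power_law <- function(records, exponent = "free",
                          method = c("log", "nls")) {
  method <- match.arg(method)
  records <- normalize_records(records)
  free_exponent <- identical(exponent, "free")
  if (!free_exponent) {
    check_number(exponent, "exponent")
  }

  if (any(records$pc_pa < 0)) {
    pt_abort("`pc_pa` must be non-negative.", "invalid_input")
  }
  n_zero <- sum(records$pc_pa == 0)
  if (n_zero > 0) {
    pt_warn(sprintf("Dropping %d record(s) with pc_pa = 0 (free passage).",
                    n_zero), "dropped_records")
    records <- dplyr::filter(records, .data$pc_pa > 0)
  }

  n_par <- if (free_exponent) 2L else 1L
  if (nrow(records) < max(3L, n_par + 1L)) {
    pt_abort("At least 3 informative records are required to fit the model.",
             "insufficient_data")
  }

  ratio <- records$diameter_um / records$gap_um
  lratio <- log(ratio)
  if (free_exponent &&
      diff(range(lratio)) < 1e-8 * max(1, abs(mean(lratio)))) {
    pt_abort(
      "All records share one diameter/gap ratio: the exponent is unidentifiable.",
      "unidentifiable_model")
  }

  y <- log(records$pc_pa) - log(records$E_pa)
  if (method == "log") {
    if (free_exponent) {
      ft <- lm(y ~ lratio)
      cf <- exp(coef(ft)[[1]])
      ex <- coef(ft)[[2]]
    } else {
      cf <- exp(mean(y - exponent * lratio))
      ex <- exponent
    }
  } else {
    fit_one <- function(n0) {
      df <- tibble(pc = records$pc_pa, E = records$E_pa, r = ratio)
      start_c <- exp(mean(y - n0 * log(df$r)))
      if (free_exponent) {
        minpack.lm::nlsLM(pc ~ cc * E * r^nn, data = df,
                          start = list(cc = start_c, nn = n0),
                          lower = c(cc = 1e-12, nn = 0.5),
                          upper = c(cc = Inf, nn = 4),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(pc ~ cc * E * r^exponent, data = df,
                          start = list(cc = start_c),
                          lower = c(cc = 1e-12),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }
    starts <- if (free_exponent) c(1, 2, 3) else 2
    fits <- lapply(starts, function(n0) tryCatch(fit_one(n0),
                                                 error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) {
      pt_abort("Nonlinear least-squares fit failed from all starts.",
               "numerical_error")
    }
    best <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
    cf <- coef(best)[["cc"]]
    ex <- if (free_exponent) coef(best)[["nn"]] else exponent
  }

  if (!is.finite(cf) || cf <= 0 || !is.finite(ex) || ex <= 0) {
    pt_warn("Fitted parameters fall outside the physical range (c, n > 0).",
            "unphysical_fit")
  }
  mod <- structure(list(coefficient = cf, exponent = ex),
                   class = "power_law_model")

  pred <- pc_formula(cf, ex, records$E_pa, records$diameter_um,
                     records$gap_um)
  res_pa <- records$pc_pa - pred
  res_log <- log(records$pc_pa) - log(pred)
  dof <- nrow(records) - n_par
  ss_tot <- sum((records$pc_pa - mean(records$pc_pa))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res_pa^2) / ss_tot else NA_real_
  out <- structure(
    list(model = mod,
         r_squared = r2,
         se_log = sqrt(sum(res_log^2) / dof),
         se_pa = sqrt(sum(res_pa^2) / dof),
         n_points = nrow(records),
         residuals_pa = res_pa,
         fitted_pa = pred,
         exponent_mode = if (free_exponent) "free" else exponent,
         method = method,
         data = records),
    class = "pc_fit")
  if (!is.na(r2) && r2 < 0) {
    pt_warn("R-squared is negative: the fit is worse than a constant (degenerate).",
            "degenerate_fit")
  }
  out
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf(
    "<pc_fit> Pc = %.5g * E * (a/g)^%.5g  [%s exponent, %s objective]\n",
    x$model$coefficient, x$model$exponent,
    if (identical(x$exponent_mode, "free")) "free" else "fixed", x$method))
  cat(sprintf("  n = %d, R2 (pressure scale) = %.4f, SE(log) = %.4g, SE(Pa) = %.4g\n",
              x$n_points, x$r_squared, x$se_log, x$se_pa))
  invisible(x)
}

#' @describeIn fit_power_law Coefficient-level summary of a `pc_fit`.
#' @param x,object A `pc_fit` object.
#' @param ... Unused.
#' @export
tidy.pc_fit <- function(x, ...) {
  tibble(term = c("coefficient", "exponent"),
         estimate = c(x$model$coefficient, x$model$exponent))
}

#' @describeIn fit_power_law One-row goodness-of-fit summary of a `pc_fit`.
#' @export
glance.pc_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, se_log = x$se_log, se_pa = x$se_pa,
         n_points = x$n_points, coefficient = x$model$coefficient,
         exponent = x$model$exponent, method = x$method)
}

#' @describeIn fit_power_law Input records with fitted values and residuals.
#' @export
augment.pc_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted_pa, .resid = x$residuals_pa)
}

#' @describeIn fit_power_law Observed-versus-fitted diagnostic plot.
#' @export
autoplot.pc_fit <- function(object, ...) {
  ggplot2::ggplot(augment(object),
                  ggplot2::aes(x = .data$.fitted, y = .data$pc_pa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fitted critical pressure (Pa)",
                  y = "Observed critical pressure (Pa)",
                  title = sprintf("Pc = %.3g E (a/g)^%.3g,  R2 = %.3f",
                                  object$model$coefficient,
                                  object$model$exponent, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Compare linear, quadratic and cubic critical-pressure models
#'
#' Fits `Pc = c * E * (a/g)^n` with the exponent fixed at each candidate
#' order and ranks the fits by goodness of fit on the pressure scale.
#' Ties in R-squared are broken in favour of the lower (more parsimonious)
#' exponent.
#'
#' @inheritParams fit_power_law
#' @param exponents Candidate integer exponents. Default `c(1, 2, 3)`.
#'
#' @return A tibble with one row per candidate, ordered best-first, columns
#'   `rank`, `exponent`, `coefficient`, `r_squared`, `se_log`, `se_pa`,
#'   `n_points`; the full `pc_fit` objects are attached as attribute
#'   `"fits"` (in the ranked order).
#' @examples
#' grid <- tidyr::expand_grid(E_pa = c(350, 650), diameter_um = c(12, 17, 25),
#'                            gap_um = c(4, 8)) |>
#'   dplyr::mutate(pc_pa = 0.027 * E_pa * (diameter_um / gap_um)^2)
#' compare_model_orders(grid)
#' @export
compare_model_orders <- function(records, exponents = c(1, 2, 3),
                                 method = c("log", "nls")) {
  method <- match.arg(method)
  fits <- lapply(exponents, function(n) {
    fit_power_law(records, exponent = n, method = method)
  })
  tab <- purrr::map_dfr(fits, glance)
  ord <- order(-tab$r_squared, tab$exponent)
  tab <- dplyr::mutate(tab[ord, ], rank = dplyr::row_number(),
                       .before = 1)
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Validate a critical-pressure model against measured gap/pressure pairs
#'
#' Predicts the critical pressure of one cell type at each observed gap and
#' compares against the measurements: the coefficient of determination is
#' computed about the identity line (observed vs predicted), and the Pearson
#' correlation between observed and predicted values is reported alongside.
#' A perfect model gives (1, 1); a constant offset preserves r = 1 but
#' lowers R-squared.
#'
#' @param model A [power_law_model()].
#' @param cell A [cell_spec()] describing the measured cell type.
#' @param observations Data frame with columns `gap_um` and `pc_pa`
#'   (measured critical pressures, Pa). At least 3 rows.
#'
#' @return A one-row tibble with `r_squared`, `pearson_r` and `n`.
#' @examples
#' cell <- cell_spec(17, 430)
#' obs <- tibble::tibble(gap_um = c(5, 6, 8),
#'                       pc_pa = predict_critical_pressure(cell, c(5, 6, 8)))
#' validate_against(power_law_model(), cell, obs)
#' @export
validate_against <- function(model, cell, observations) {
  if (!is.data.frame(observations) ||
      !all(c("gap_um", "pc_pa") %in% names(observations))) {
    pt_abort("`observations` needs columns `gap_um` and `pc_pa`.",
             "invalid_input")
  }
  if (nrow(observations) < 3) {
    pt_abort("At least 3 observations are required.", "insufficient_data")
  }
  obs <- observations$pc_pa
  pred <- vapply(observations$gap_um, function(g) {
    predict_critical_pressure(cell, g, model)
  }, numeric(1))
  if (stats::sd(obs) == 0) {
    pt_abort("Observations are constant: correlation is undefined.",
             "undefined_correlation")
  }
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  tibble(r_squared = r2, pearson_r = cor(obs, pred), n = length(obs))
}
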