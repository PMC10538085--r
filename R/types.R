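#' Specify a single cell
#'
#' A cell is idealised as a homogeneous, isotropic, neo-Hookean elastic sphere
#' characterised by its diameter, effective Young's modulus and Poisson ratio.
#' The effective modulus is the whole-cell value measured by e.g. AFM or
#' micropipette aspiration, which folds the nucleus and cytoskeleton into one
#' number.
#'
#' @param diameter_um Cell diameter in micrometres (must be > 0).
#' @param youngs_modulus_pa Effective Young's modulus in pascals (must be > 0).
#'   Measured values for A549 lung-cancer cells span roughly 350-650 Pa.
#' @param poisson_ratio Poisson ratio, strictly between 0 and 0.5.
#'   Default 0.3, appropriate for the cell periphery in contact problems.
#'
#' @return An object of class `cell_spec`: a named list with the validated
#'   fields above.
#' @examples
#' cell_spec(17, 430)
#' @export
cell_spec <- function(diameter_um, youngs_modulus_pa, poisson_ratio = 0.3) {
  check_number(diameter_um, "diameter_um")
  check_number(youngs_modulus_pa, "youngs_modulus_pa")
  if (!is.numeric(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    pt_abort("`poisson_ratio` must lie strictly between 0 and 0.5.",
             "invalid_input")
  }
  structure(
    list(diameter_um = as.numeric(diameter_um),
         youngs_modulus_pa = as.numeric(youngs_modulus_pa),
         poisson_ratio = as.numeric(poisson_ratio)),
    class = "cell_spec"
  )
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf("<cell_spec> d = %.3g um, E = %.3g Pa, nu = %.3g\n",
              x$diameter_um, x$youngs_modulus_pa, x$poisson_ratio))
  invisible(x)
}

#' Geometry of one trapping unit
#'
#' A trapping unit is the space between two adjacent diamond-shaped pillars.
#' The pillars are rhombic prisms described by their two in-plane diagonals
#' and out-of-plane height; the facing vertices are rounded with a fillet and
#' separated by the gap, the narrowest clearance a cell must squeeze through.
#'
#' @param gap_um Gap (minimum pillar-to-pillar clearance), micrometres.
#' @param diagonal_major_um Pillar diagonal along the flow direction,
#'   micrometres. Default 70.
#' @param diagonal_minor_um Pillar diagonal across the flow direction,
#'   micrometres. Default 70. The gap must be smaller than this diagonal.
#' @param height_um Pillar (channel) height, micrometres. Default 50.
#' @param fillet_radius_um Rounding radius of the pillar vertices,
#'   micrometres, >= 0. Default 2.
#'
#' @return An object of class `trap_geometry`.
#' @examples
#' trap_geometry(8)
#' @export
trap_geometry <- function(gap_um,
                          diagonal_major_um = 70,
                          diagonal_minor_um = 70,
                          height_um = 50,
                          fillet_radius_um = 2) {
  check_number(gap_um, "gap_um")
  check_number(diagonal_major_um, "diagonal_major_um")
  check_number(diagonal_minor_um, "diagonal_minor_um")
  check_number(height_um, "height_um")
  check_number(fillet_radius_um, "fillet_radius_um", positive = FALSE)
  if (fillet_radius_um < 0) {
    pt_abort("`fillet_radius_um` must be >= 0.", "invalid_input")
  }
  if (gap_um >= diagonal_minor_um) {
    pt_abort("`gap_um` must be smaller than `diagonal_minor_um`.",
             "invalid_geometry")
  }
  structure(
    list(gap_um = as.numeric(gap_um),
         diagonal_major_um = as.numeric(diagonal_major_um),
         diagonal_minor_um = as.numeric(diagonal_minor_um),
         height_um = as.numeric(height_um),
         fillet_radius_um = as.numeric(fillet_radius_um)),
    class = "trap_geometry"
  )
}

#' @export
print.trap_geometry <- function(x, ...) {
  cat(sprintf(
    "<trap_geometry> gap = %.3g um, diagonals = %.3g x %.3g um, height = %.3g um, fillet = %.3g um\n",
    x$gap_um, x$diagonal_major_um, x$diagonal_minor_um, x$height_um,
    x$fillet_radius_um))
  invisible(x)
}

#' Power-law critical-pressure model
#'
#' The empirical relation for the critical pressure at which a trapped cell
#' escapes through a pillar gap:
#' \deqn{P_c = c \, E \, (a/g)^n}
#' with `a` the cell diameter, `g` the gap, `E` the cell Young's modulus,
#' coefficient `c` and exponent `n`. The defaults `c = 0.027`, `n = 2` are
#' the published calibration for diamond-pillar traps; both can be refitted
#' from sweep data with [fit_power_law()].
#'
#' @param coefficient Dimensionless prefactor `c` (> 0). Default 0.027.
#' @param exponent Exponent `n` of the diameter-to-gap ratio (> 0). Default 2.
#'
#' @return An object of class `power_law_model`.
#' @examples
#' power_law_model()
#' @export
power_law_model <- function(coefficient = 0.027, exponent = 2) {
  check_number(coefficient, "coefficient")
  check_number(exponent, "exponent")
  structure(
    list(coefficient = as.numeric(coefficient),
         exponent = as.numeric(exponent)),
    class = "power_law_model"
  )
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("<power_law_model> Pc = %.4g * E * (a/g)^%.4g\n",
              x$coefficient, x$exponent))
  invisible(x)
}

#' Neo-Hookean material parameters from engineering constants
#'
#' Converts small-strain Young's modulus and Poisson ratio to the
#' (C10, D1) parameterisation of the compressible neo-Hookean strain energy
#' \deqn{W = C_{10}(\bar I_1 - 3) + (1/D_1)(J - 1)^2}
#' using `C10 = E / (4 (1 + nu))` and `D1 = 6 (1 - 2 nu) / E`, the
#' conventional conversion for this energy form.
#'
#' @param youngs_modulus_pa Young's modulus, Pa.
#' @param poisson_ratio Poisson ratio in (0, 0.5). Default 0.3.
#'
#' @return An object of class `material_nh` with fields `c10_pa`,
#'   `d1_inv_pa`, `source_modulus_pa` and `source_poisson`.
#' @examples
#' material_nh(430)
#' @export
material_nh <- function(youngs_modulus_pa, poisson_ratio = 0.3) {
  check_number(youngs_modulus_pa, "youngs_modulus_pa")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    pt_abort("`poisson_ratio` must lie strictly between 0 and 0.5.",
             "invalid_input")
  }
  structure(
    list(c10_pa = youngs_modulus_pa / (4 * (1 + poisson_ratio)),
         d1_inv_pa = 6 * (1 - 2 * poisson_ratio) / youngs_modulus_pa,
         source_modulus_pa = youngs_modulus_pa,
         source_poisson = poisson_ratio),
    class = "material_nh"
  )
}

#' @export
print.material_nh <- function(x, ...) {
  cat(sprintf("<material_nh> C10 = %.4g Pa, D1 = %.4g 1/Pa (E = %.4g Pa, nu = %.3g)\n",
              x$c10_pa, x$d1_inv_pa, x$source_modulus_pa, x$source_poisson))
  invisible(x)
}
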