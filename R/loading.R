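# Parabolic hydrodynamic loading of the cell's upstream surface.  The
# carrier flow is not resolved around the moving cell; its push is idealised
# as a pressure field acting along the flow axis (+x), peaking on the cell
# axis and vanishing at the cell radius.

#' Parabolic pressure load on a cell
#'
#' The load applied to the upstream region of the cell surface is
#' `P0 * f(y, z)` with the parabolic profile
#' \deqn{f(y, z) = 1 - (y^2 + z^2) / r^2}
#' where `(y, z)` are measured from the cell centroid in the plane normal to
#' the flow and `r` is the cell radius. Outside the disk of radius `r` the
#' factor is clamped to zero. The load acts along the fixed flow axis (+x).
#'
#' @param magnitude_pa Peak pressure `P0` at the cell axis, Pa (>= 0).
#' @param cell_radius_um Cell radius `r`, micrometres (> 0).
#'
#' @return An object of class `parabolic_load`.
#' @examples
#' parabolic_load(50, 8.5)
#' @export
parabolic_load <- function(magnitude_pa, cell_radius_um) {
  check_number(magnitude_pa, "magnitude_pa", positive = FALSE)
  if (magnitude_pa < 0) {
    pt_abort("`magnitude_pa` must be >= 0.", "invalid_input")
  }
  check_number(cell_radius_um, "cell_radius_um")
  structure(
    list(magnitude_pa = as.numeric(magnitude_pa),
         cell_radius_um = as.numeric(cell_radius_um),
         direction = c(1, 0, 0)),
    class = "parabolic_load"
  )
}

#' @export
print.parabolic_load <- function(x, ...) {
  cat(sprintf("<parabolic_load> P0 = %.4g Pa, r = %.4g um, direction +x\n",
              x$magnitude_pa, x$cell_radius_um))
  invisible(x)
}

#' Dimensionless parabolic profile factor
#'
#' Evaluates `f(y, z) = 1 - (y^2 + z^2) / r^2`, clamped to zero outside the
#' loaded disk, so the result always lies in [0, 1].
#'
#' @param load A [parabolic_load()].
#' @param y,z Transverse coordinates relative to the cell centroid,
#'   micrometres (vectorised).
#'
#' @return Numeric vector of profile factors in [0, 1].
#' @examples
#' l <- parabolic_load(50, 10)
#' field_factor(l, y = c(0, 5, 10), z = 0)
#' @export
field_factor <- function(load, y, z) {
  stopifnot(inherits(load, "parabolic_load"))
  r2 <- load$cell_radius_um^2
  pmax(0, 1 - (y^2 + z^2) / r2)
}

#' Resultant force of the full parabolic load
#'
#' Integrating `P0 * f(y, z)` over the loaded disk of radius `r` gives the
#' closed form `P0 * pi * r^2 / 2`: the parabolic profile halves the force a
#' uniform pressure would exert on the same disk. Forces are in piconewtons
#' because 1 Pa x 1 um^2 = 1 pN.
#'
#' @param load A [parabolic_load()].
#' @return Resultant force along +x, piconewtons.
#' @examples
#' load_resultant(parabolic_load(50, 8.5))
#' @export
load_resultant <- function(load) {
  stopifnot(inherits(load, "parabolic_load"))
  load$magnitude_pa * pi * load$cell_radius_um^2 / 2
}

#' Apply the parabolic load to surface points
#'
#' Assigns each surface point a traction vector along the flow axis: points
#' in the front (upstream) region receive `P0 * f(y - yc, z - zc)` in +x,
#' all other points receive zero. The front region is the set of points at
#' or upstream of the centroid (`x <= xc`), mirroring the partition of the
#' cell surface into a loaded upstream half and an unloaded downstream half.
#'
#' @param load A [parabolic_load()].
#' @param points Data frame with columns `x`, `y`, `z` (micrometres) giving
#'   surface point positions.
#' @param centroid Optional numeric length-3 cell centroid; defaults to the
#'   column means of `points`.
#'
#' @return `points` as a tibble with traction columns `t_x`, `t_y`, `t_z`
#'   (Pa) appended.
#' @examples
#' pts <- tibble::tibble(x = c(-1, 1), y = 0, z = 0)
#' apply_traction(parabolic_load(10, 2), pts)
#' @export
apply_traction <- function(load, points, centroid = NULL) {
  stopifnot(inherits(load, "parabolic_load"))
  if (!is.data.frame(points) || !all(c("x", "y", "z") %in% names(points))) {
    pt_abort("`points` needs columns `x`, `y`, `z`.", "invalid_input")
  }
  points <- as_tibble(points)
  centroid <- centroid %||% c(mean(points$x), mean(points$y), mean(points$z))
  front <- points$x <= centroid[1]
  if (!any(front)) {
    pt_warn("Front-region selection is empty: all tractions are zero.",
            "empty_selection")
  }
  f <- field_factor(load, points$y - centroid[2], points$z - centroid[3])
  tx <- ifelse(front, load$magnitude_pa * f, 0)
  dplyr::mutate(points, t_x = tx, t_y = 0, t_z = 0)
}
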