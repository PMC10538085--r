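# Quasi-static contact simulation of a neo-Hookean cell pushed against the
# pillar gap by the parabolic load, and bisection search for the critical
# escape pressure.
#
# The load is ramped in increments; within each increment the total
# potential energy (hyperelastic strain energy - dead-load work + contact
# penalty) is minimised with a Barzilai-Borwein descent with Armijo
# backtracking.  A trapped cell reaches a static equilibrium upstream of the
# throat; above the critical pressure no equilibrium exists and the
# minimiser slides the cell through the gap, which is detected from the
# centroid crossing the throat plane by one cell radius.

#' Solver settings for the contact simulator
#'
#' @param resolution Cell-mesh lattice divisions per axis (see
#'   [cell_mesh()]). Default 6 (about 1300 tetrahedra).
#' @param n_increments Load ramp increments. Default 6.
#' @param max_iter Maximum minimiser iterations per increment. Default 1500.
#' @param settle_rounds Maximum re-equilibration rounds at full load (the
#'   front-region selection is refreshed between rounds). Default 30.
#' @param tol_rel Convergence tolerance on the residual nodal force,
#'   relative to the force scale `E * h^2` of one element face. Default 2e-5.
#' @param penalty_scale Contact penalty stiffness in units of `E / h`
#'   (element-edge-scaled, approximating hard pressure overclosure).
#'   Default 100.
#' @param penetration_tol_frac Accepted contact penetration as a fraction of
#'   the gap. Default 0.01.
#' @param escape_margin_radii Distance past the throat plane (in cell radii)
#'   at which the cell counts as escaped. The passage transition is a
#'   snap-through (equilibria jump from well upstream to well downstream of
#'   the throat), so the classification is insensitive to the exact margin;
#'   a small margin just past the throat detects the snap while pre-snap
#'   equilibria always keep the centroid upstream. Default 0.1.
#'
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(resolution = 6, n_increments = 6, max_iter = 1500,
                        settle_rounds = 30, tol_rel = 2e-5,
                        penalty_scale = 100, penetration_tol_frac = 0.01,
                        escape_margin_radii = 0.1) {
  structure(list(resolution = resolution, n_increments = n_increments,
                 max_iter = max_iter, settle_rounds = settle_rounds,
                 tol_rel = tol_rel, penalty_scale = penalty_scale,
                 penetration_tol_frac = penetration_tol_frac,
                 escape_margin_radii = escape_margin_radii),
            class = "sim_control")
}

# Precompute reference element data for the energy kernel
mesh_ref_data <- function(mesh) {
  ntet <- mesh$n_tets
  dminv <- matrix(0, 9, ntet)
  nd <- mesh$nodes
  tt <- mesh$tets
  for (e in seq_len(ntet)) {
    Dm <- cbind(nd[tt[e, 2], ] - nd[tt[e, 1], ],
                nd[tt[e, 3], ] - nd[tt[e, 1], ],
                nd[tt[e, 4], ] - nd[tt[e, 1], ])
    dminv[, e] <- as.vector(solve(Dm))
  }
  dminv
}

# Nodal force vector (pN) of the hydrodynamic push: the upstream-facing
# part of the surface is loaded with the parabolic pressure P0 * f(y, z)
# acting along the inward surface normal (a pressure, as the carrier fluid
# exerts), which both drives the cell in +x and squeezes the rear bulge
# toward the axis while it feeds through the waist.  The profile weight is
# pinned to the material surface (evaluated on the reference sphere), while
# the loaded selection and facet normals are refreshed from the current
# configuration at the start of each increment, then held frozen so each
# minimisation works on a conservative (dead) load.
build_fext <- function(xvec, mesh, load) {
  n <- mesh$n_nodes
  xs <- matrix(xvec, ncol = 3, byrow = TRUE)
  ctr_x <- mean(xs[, 1])
  t1 <- mesh$tris[, 1]; t2 <- mesh$tris[, 2]; t3 <- mesh$tris[, 3]
  p1 <- xs[t1, , drop = FALSE]
  e1 <- xs[t2, , drop = FALSE] - p1
  e2 <- xs[t3, , drop = FALSE] - p1
  avec <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  # wetted selection: rear-facing facets (outward normal against the flow),
  # i.e. every part of the surface the upstream fluid pushes on
  upstream <- avec[, 1] < 0
  nd0 <- mesh$nodes                      # reference sphere centred at 0
  fc0y <- (nd0[t1, 2] + nd0[t2, 2] + nd0[t3, 2]) / 3
  fc0z <- (nd0[t1, 3] + nd0[t2, 3] + nd0[t3, 3]) / 3
  p_fac <- ifelse(upstream, load$magnitude_pa * field_factor(load, fc0y, fc0z), 0)
  ftri <- -avec * p_fac                  # pressure: -p * (outward area vector)
  fext <- numeric(3 * n)
  for (d in 1:3) {
    idx <- 3 * (c(t1, t2, t3) - 1) + d
    agg <- tapply(rep(ftri[, d] / 3, 3), idx, sum)
    fext[as.integer(names(agg))] <- fext[as.integer(names(agg))] +
      as.numeric(agg)
  }
  fext
}

centroid_x <- function(xvec) mean(xvec[seq(1, length(xvec), by = 3)])

# Projection of a configuration (or gradient) onto the subspace that is
# mirror-symmetric about the y = 0 and z = 0 planes.  The cell, pillars and
# load share both symmetries, so the physical solution lives here; the
# projection also removes the spurious rigid tumbling/drift modes that a
# node-attached dead load would otherwise feed.
make_symmetrizer <- function(mesh) {
  iy <- mesh$mirror_y
  iz <- mesh$mirror_z
  function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    m <- (m + cbind(m[iy, 1], -m[iy, 2], m[iy, 3])) / 2
    m <- (m + cbind(m[iz, 1], m[iz, 2], -m[iz, 3])) / 2
    as.vector(t(m))
  }
}

# Limited-memory BFGS minimisation of the incremental potential, with an
# early stop when the escape criterion fires mid-minimisation (signalled
# out of the objective as a classed condition).  Inverted trial states get
# a large finite energy so the line search backs off.
lbfgs_minimize <- function(x, fg, sym, maxit, pgtol, stop_fn = NULL) {
  env <- new.env(parent = emptyenv())
  env$g <- numeric(length(x))
  env$x <- x
  env$n <- 0L
  fn <- function(xx) {
    env$n <- env$n + 1L
    r <- fg(xx)
    if (!is.finite(r$energy)) {
      return(1e30)
    }
    env$g <- sym(r$grad)
    env$x <- xx
    if (!is.null(stop_fn) && stop_fn(xx)) {
      rlang::abort("escape", class = "pillartrap_stop_escape")
    }
    r$energy
  }
  gr <- function(xx) env$g
  res <- tryCatch(
    stats::optim(x, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e7, pgtol = pgtol,
                                lmm = 8)),
    pillartrap_stop_escape = function(e) NULL)
  if (is.null(res)) {
    list(x = env$x, status = "stopped", n_eval = env$n)
  } else {
    list(x = res$par,
         status = if (res$convergence == 0) "converged" else "maxiter",
         n_eval = env$n)
  }
}

#' Simulate a loaded cell against the pillar gap
#'
#' Advances a quasi-static incremental solution of a neo-Hookean spherical
#' cell pushed by the parabolic load against the rigid pillar pair, with
#' frictionless penalty contact. The cell either reaches a trapped static
#' equilibrium or escapes through the gap; escape is declared when the cell
#' centroid passes the gap-throat plane by more than one cell radius.
#'
#' @param mesh A [cell_mesh()] (centred at the origin).
#' @param material A [material_nh()].
#' @param surface A `rigid_surface` from [build_pillar_surface()].
#' @param load A [parabolic_load()]; its magnitude is the peak pressure P0.
#' @param control A [sim_control()].
#' @param position Optional length-3 initial centre position (micrometres).
#'   Default: on the flow axis, tangent to the upstream pillar faces.
#' @param init_nodes Optional node-position matrix (from a previous
#'   `sim_outcome$final_nodes`) to continue from, e.g. an equilibrium at a
#'   lower pressure. Used by [find_critical_pressure()] to ramp the pressure
#'   quasi-statically between trials.
#' @param ramp Optional increasing vector of load factors in (0, 1] ending
#'   at 1. Default: geometric doubling ramp `2^-(k-1), ..., 1/2, 1` with
#'   `k = n_increments` steps.
#'
#' @return An object of class `sim_outcome` with fields `escaped`,
#'   `converged`, `centroid_path` (tibble: stage, load factor, centroid x),
#'   `max_principal_stretch`, `max_penetration_um`, `min_j`, `n_evals` and
#'   the final node positions.
#' @export
simulate_passage <- function(mesh, material, surface, load,
                             control = sim_control(), position = NULL,
                             init_nodes = NULL, ramp = NULL) {
  stopifnot(inherits(mesh, "cell_mesh"), inherits(material, "material_nh"),
            inherits(surface, "rigid_surface"),
            inherits(load, "parabolic_load"))
  r_cell <- mesh$diameter_um / 2
  if (is.null(init_nodes)) {
    position <- position %||% c(initial_mesh_x(surface, mesh), 0, 0)
    nodes0 <- sweep(mesh$nodes, 2, position, `+`)
    if (min(pillar_sdf(surface, nodes0[mesh$surf_nodes, 1],
                       nodes0[mesh$surf_nodes, 2])) < -1e-6) {
      pt_abort("Initial cell position intersects the pillars.",
               "invalid_input")
    }
  } else {
    stopifnot(is.matrix(init_nodes), nrow(init_nodes) == mesh$n_nodes)
    nodes0 <- init_nodes
  }
  x <- as.vector(t(nodes0))
  dminv <- mesh_ref_data(mesh)
  E <- material$source_modulus_pa
  kpen <- control$penalty_scale * E / mesh$h_edge
  kvol <- 1 / material$d1_inv_pa
  tol_g <- control$tol_rel * E * mesh$h_edge^2
  throat <- surface$gap_throat_x
  margin <- control$escape_margin_radii * r_cell
  escaped_at <- function(xv) centroid_x(xv) > throat + margin

  sym <- make_symmetrizer(mesh)
  x <- sym(x)
  make_fg <- function(fext) {
    function(xv) {
      r <- nh_energy_grad(xv, mesh$tets, dminv, mesh$volumes,
                          material$c10_pa, kvol, fext, mesh$surf_nodes,
                          mesh$surf_weights, surface$inner_a,
                          surface$inner_b, surface$fillet,
                          surface$center_y, kpen)
      list(energy = r$energy, grad = r$grad, max_pen = r$max_pen,
           min_j = r$min_j)
    }
  }
  state_metrics <- function(xv) {
    pen <- nh_max_penetration(xv, mesh$surf_nodes, surface$inner_a,
                              surface$inner_b, surface$fillet,
                              surface$center_y)
    fdg <- nh_def_grads(xv, mesh$tets, dminv)
    js <- vapply(seq_len(ncol(fdg)), function(e) det(matrix(fdg[, e], 3, 3)),
                 numeric(1))
    list(pen = pen, min_j = min(js))
  }

  path <- list()
  record <- function(stage, s, xv) {
    path[[length(path) + 1L]] <<- tibble(stage = stage, load_factor = s,
                                         centroid_x_um = centroid_x(xv))
  }
  record("initial", 0, x)

  escaped <- FALSE
  converged <- FALSE
  n_evals <- 0L
  max_pen <- 0
  min_j <- Inf
  note_state <- function(xv) {
    sm <- state_metrics(xv)
    max_pen <<- max(max_pen, sm$pen)
    min_j <<- min(min_j, sm$min_j)
  }
  ramp <- ramp %||% 2^-(control$n_increments - seq_len(control$n_increments))
  stopifnot(all(diff(ramp) > 0), abs(tail(ramp, 1) - 1) < 1e-12)

  for (s in ramp) {
    lseg <- parabolic_load(s * load$magnitude_pa, load$cell_radius_um)
    fext <- build_fext(x, mesh, lseg)
    res <- lbfgs_minimize(x, make_fg(fext), sym, control$max_iter, tol_g,
                          stop_fn = escaped_at)
    x <- res$x
    n_evals <- n_evals + res$n_eval
    record("ramp", s, x)
    if (res$status == "stopped" || escaped_at(x)) {
      escaped <- TRUE
      break
    }
    note_state(x)
  }

  if (!escaped) {
    # settle at full load, refreshing the front-region selection as the
    # cell advances, until the configuration stops moving
    for (k in seq_len(control$settle_rounds)) {
      x_prev <- x
      fext <- build_fext(x, mesh, load)
      res <- lbfgs_minimize(x, make_fg(fext), sym, control$max_iter, tol_g,
                            stop_fn = escaped_at)
      x <- res$x
      n_evals <- n_evals + res$n_eval
      record("settle", 1, x)
      if (res$status == "stopped" || escaped_at(x)) {
        escaped <- TRUE
        break
      }
      note_state(x)
      moved <- max(abs(x - x_prev))
      if (res$status == "converged" && moved < 1e-3 * mesh$h_edge) {
        converged <- TRUE
        break
      }
    }
    if (!escaped && !converged) {
      pt_warn("No static equilibrium within budget; treating as trapped.",
              "not_converged")
    }
  }

  fdg <- nh_def_grads(x, mesh$tets, dminv)
  stretch <- sqrt(max(vapply(seq_len(ncol(fdg)), function(e) {
    f <- matrix(fdg[, e], 3, 3)
    max(eigen(crossprod(f), symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))))

  structure(
    list(escaped = escaped,
         converged = escaped || converged,
         centroid_path = dplyr::bind_rows(path),
         max_principal_stretch = stretch,
         max_penetration_um = max_pen,
         penetration_tol_um = control$penetration_tol_frac *
           surface$geometry$gap_um,
         min_j = min_j,
         n_evals = n_evals,
         final_nodes = matrix(x, ncol = 3, byrow = TRUE),
         load = load, control = control),
    class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf(
    "<sim_outcome> %s (converged: %s); centroid x = %.3g um, max stretch %.3f, max penetration %.3g um\n",
    if (x$escaped) "ESCAPED" else "TRAPPED", x$converged,
    tail(x$centroid_path$centroid_x_um, 1), x$max_principal_stretch,
    x$max_penetration_um))
  invisible(x)
}

#' Critical escape pressure of one cell/gap combination
#'
#' Estimates the minimum peak load pressure at which the cell squeezes
#' through the gap. An escape bracket is found by doubling the pressure from
#' `p_start`; bisection (with [simulate_passage()] as the trapped/escaped
#' oracle, assuming escape is monotone in pressure) then narrows the bracket
#' until its width is at most `tolerance_rel` of the upper end. The reported
#' critical pressure is the upper (escaping) end of the final bracket.
#' Cells no larger than the gap pass freely: the critical pressure is zero
#' and no simulation is run.
#'
#' @param cell A [cell_spec()].
#' @param geometry A [trap_geometry()].
#' @param tolerance_rel Relative bracket-width tolerance. Default 0.05.
#' @param p_start Starting pressure for the doubling search, Pa. Default 1.
#' @param control A [sim_control()].
#' @param seed Optional integer recorded with the result (the solver itself
#'   is deterministic).
#' @param mesh Optional pre-built [cell_mesh()] matching `cell` (reused
#'   across calls in sweeps).
#'
#' @return An object of class `critical_pressure_result`: `pc_pa`, the final
#'   `bracket` (trapped, escaped), `iterations` (simulations run),
#'   `tolerance_pa`, and solver metadata.
#' @export
find_critical_pressure <- function(cell, geometry, tolerance_rel = 0.05,
                                   p_start = 1, control = sim_control(),
                                   seed = NULL, mesh = NULL) {
  stopifnot(inherits(cell, "cell_spec"), inherits(geometry, "trap_geometry"))
  a <- cell$diameter_um
  g <- geometry$gap_um
  if (a <= g) {
    return(structure(
      list(pc_pa = 0, bracket = c(0, 0), iterations = 0L,
           tolerance_pa = 0, cell = cell, geometry = geometry,
           seed = seed, control = control),
      class = "critical_pressure_result"))
  }
  surface <- build_pillar_surface(geometry)
  mesh <- mesh %||% cell_mesh(a, control$resolution)
  material <- material_nh(cell$youngs_modulus_pa, cell$poisson_ratio)
  n_sim <- 0L
  state <- NULL     # node positions of the last trapped equilibrium
  state_p <- 0      # ... and the pressure it was equilibrated at
  escapes <- function(p) {
    n_sim <<- n_sim + 1L
    o <- if (is.null(state)) {
      simulate_passage(mesh, material, surface, parabolic_load(p, a / 2),
                       control)
    } else {
      # quasi-static continuation: ramp from the trapped equilibrium at the
      # highest pressure seen so far up to the trial pressure
      fr <- exp(seq(log(state_p / p), 0, length.out = 4))[-1]
      simulate_passage(mesh, material, surface, parabolic_load(p, a / 2),
                       control, init_nodes = state, ramp = fr)
    }
    if (!o$escaped) {
      state <<- o$final_nodes
      state_p <<- p
    }
    o$escaped
  }

  lo <- 0
  p <- p_start
  for (d in 1:40) {
    if (escapes(p)) break
    lo <- p
    p <- 2 * p
    if (d == 40) {
      pt_abort("No escape found while doubling the pressure bracket.",
               "numerical_error")
    }
  }
  hi <- p
  while (hi - lo > tolerance_rel * hi) {
    mid <- (lo + hi) / 2
    if (escapes(mid)) hi <- mid else lo <- mid
  }
  structure(
    list(pc_pa = hi, bracket = c(lo, hi), iterations = n_sim,
         tolerance_pa = tolerance_rel * hi, cell = cell,
         geometry = geometry, seed = seed, control = control),
    class = "critical_pressure_result")
}

#' @export
print.critical_pressure_result <- function(x, ...) {
  cat(sprintf(
    "<critical_pressure_result> Pc = %.4g Pa (bracket %.4g-%.4g Pa, %d simulations)\n",
    x$pc_pa, x$bracket[1], x$bracket[2], x$iterations))
  invisible(x)
}

#' Critical-pressure sweep over cell and gap grids
#'
#' Runs [find_critical_pressure()] over the cross product of cell diameters,
#' moduli and gap sizes, producing the dataset consumed by
#' [fit_power_law()]. Combinations where the cell is not larger than the gap
#' are recorded with zero critical pressure without simulation. Individual
#' failed simulations are flagged and keep the sweep going.
#'
#' @param diameters_um Cell diameters, micrometres.
#' @param moduli_pa Young's moduli, Pa.
#' @param gaps_um Gap sizes, micrometres.
#' @param poisson_ratio Poisson ratio shared by all cells. Default 0.3.
#' @param tolerance_rel Bisection tolerance, see [find_critical_pressure()].
#' @param control A [sim_control()].
#' @param seed Optional integer recorded with each record.
#' @param max_ratio Upper diameter-to-gap ratio simulated. Beyond roughly
#'   five-fold squeezes the quasi-static escape search loses its monotone
#'   ordering in the gap (an internal consistency check, see the methods
#'   vignette), so such combinations are outside the solver's validated
#'   envelope; they also lie beyond the design envelope of the 25% gap
#'   rule. They are recorded as failed, not simulated. Default 5.
#'
#' @return A tibble with columns `E_pa`, `nu`, `diameter_um`, `gap_um`,
#'   `pc_pa`, `failed`; solver settings are attached as attribute
#'   `"control"`.
#' @export
sweep_critical_pressure <- function(diameters_um, moduli_pa, gaps_um,
                                    poisson_ratio = 0.3,
                                    tolerance_rel = 0.05,
                                    control = sim_control(), seed = NULL,
                                    max_ratio = 5) {
  grid <- tidyr::expand_grid(E_pa = moduli_pa, diameter_um = diameters_um,
                             gap_um = gaps_um)
  meshes <- lapply(setNames(nm = unique(grid$diameter_um)), function(d) {
    if (any(grid$diameter_um == d & d > grid$gap_um &
              d / grid$gap_um < max_ratio)) {
      cell_mesh(d, control$resolution)
    } else NULL
  })
  n_failed <- 0L
  out <- purrr::pmap_dfr(grid, function(E_pa, diameter_um, gap_um) {
    pc <- NA_real_
    failed <- FALSE
    if (diameter_um <= gap_um) {
      pc <- 0
    } else if (diameter_um / gap_um >= max_ratio) {
      failed <- TRUE
      n_failed <<- n_failed + 1L
    } else {
      res <- tryCatch(
        find_critical_pressure(
          cell_spec(diameter_um, E_pa, poisson_ratio),
          trap_geometry(gap_um), tolerance_rel = tolerance_rel,
          control = control, seed = seed,
          mesh = meshes[[as.character(diameter_um)]]),
        error = function(e) NULL)
      if (is.null(res)) {
        failed <- TRUE
        n_failed <<- n_failed + 1L
      } else {
        pc <- res$pc_pa
      }
    }
    tibble(E_pa = E_pa, nu = poisson_ratio, diameter_um = diameter_um,
           gap_um = gap_um, pc_pa = pc, failed = failed)
  })
  if (n_failed > 0) {
    pt_warn(sprintf("%d sweep point(s) failed and are flagged.", n_failed),
            "sweep_failures")
  }
  attr(out, "control") <- control
  attr(out, "seed") <- seed
  out
}
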