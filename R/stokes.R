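# Steady incompressible flow through a trapping unit: stabilised P1-P1
# finite elements on a graded tensor-product triangulation of the channel.
# Pillar interiors are excluded from the discretisation (stair-cased
# no-slip node sets, with exact grid lines on the gap edges); an optional
# depth-averaged Brinkman drag accounts for the finite channel height.
#
# Units: lengths in micrometres, velocities in um/s, pressure in Pa,
# viscosity in Pa*s (1e-3 for water).  At device scale the Reynolds number
# is small and the convective term is negligible; the solver defaults to
# Stokes flow, with a Picard iteration on the convective term available.

#' Flow conditions for a trapping-unit simulation
#'
#' @param flow_rate_ul_min Volumetric flow rate through the unit, uL/min.
#'   Device experiments use 1-10 uL/min.
#' @param density_kg_m3 Fluid density, kg/m^3. Default 1000 (water/PBS).
#' @param viscosity_pa_s Dynamic viscosity, Pa s. Default 1e-3 (1 mPa s).
#' @param channel_height_um Channel (pillar) height, micrometres. Default 50.
#'
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(flow_rate_ul_min, density_kg_m3 = 1000,
                            viscosity_pa_s = 1e-3, channel_height_um = 50) {
  check_number(flow_rate_ul_min, "flow_rate_ul_min", positive = FALSE)
  if (flow_rate_ul_min < 0) {
    pt_abort("`flow_rate_ul_min` must be >= 0.", "invalid_input")
  }
  check_number(density_kg_m3, "density_kg_m3")
  check_number(viscosity_pa_s, "viscosity_pa_s")
  check_number(channel_height_um, "channel_height_um")
  structure(
    list(flow_rate_ul_min = flow_rate_ul_min,
         density_kg_m3 = density_kg_m3,
         viscosity_pa_s = viscosity_pa_s,
         channel_height_um = channel_height_um),
    class = "flow_conditions")
}

#' @export
print.flow_conditions <- function(x, ...) {
  cat(sprintf(
    "<flow_conditions> Q = %.3g uL/min, rho = %.4g kg/m^3, mu = %.3g Pa s, h = %.3g um\n",
    x$flow_rate_ul_min, x$density_kg_m3, x$viscosity_pa_s,
    x$channel_height_um))
  invisible(x)
}

# graded symmetric 1D point set: uniform spacing hf inside [-fine_half,
# fine_half], geometric coarsening (capped at hc) out to +-half
graded_axis <- function(half, fine_half, hf, hc, grow = 1.2) {
  fine_half <- min(fine_half, half)
  pts <- seq(0, fine_half, by = hf)
  if (abs(pts[length(pts)] - fine_half) > 1e-9) pts <- c(pts, fine_half)
  x <- fine_half
  h <- hf
  while (x < half - 1e-9) {
    h <- min(h * grow, hc)
    x <- min(x + h, half)
    pts <- c(pts, x)
  }
  sort(unique(round(c(-pts, pts), 9)))
}

#' Discretise the flow domain of one trapping unit
#'
#' Builds a graded triangulated channel segment containing the two pillars
#' of a trapping unit. The side walls pass through the pillar centres (one
#' array pitch), so the visible half-pillars seal the channel and all
#' carrier flow passes through the gap. The mesh is a tensor grid,
#' refined to about one tenth of the gap inside the gap region, with grid
#' lines placed exactly on the gap edges (`y = +-gap/2`) and the throat
#' (`x = 0`).
#'
#' @param geometry A [trap_geometry()] (the gap sets the refinement scale).
#' @param length_um Channel length of the simulated segment. Default three
#'   pillar diagonals.
#' @param width_um Channel width. Default: one array pitch (`gap + 2 x`
#'   pillar half-extent), which places the side walls through the pillar
#'   centres so the visible half-pillars seal the channel and all flow
#'   passes through the central gap.
#' @param pillars Include the pillars (`FALSE` gives an empty straight
#'   channel, used for code verification against plane Poiseuille flow).
#' @param refine_um Target edge length inside the gap region. Default
#'   `gap/10`.
#'
#' @return An object of class `flow_domain`: node coordinates, triangles,
#'   solid-element mask and boundary node sets.
#' @export
flow_domain <- function(geometry, length_um = 3 * geometry$diagonal_major_um,
                        width_um = NULL, pillars = TRUE, refine_um = NULL) {
  stopifnot(inherits(geometry, "trap_geometry"))
  g <- geometry$gap_um
  surface <- build_pillar_surface(geometry)
  width_um <- width_um %||% (g + 2 * surface$apex_y)
  hf <- refine_um %||% (g / 10)

  xs <- graded_axis(length_um / 2, surface$extent_x * 0.75, hf,
                    hc = 8 * hf)
  if (pillars) {
    # exact grid lines on the gap edges, moderately fine along the pillar
    # slant, coarser near the walls
    ys_fine <- seq(-g / 2, g / 2, by = g / 10)
    y_out <- graded_axis(width_um / 2, g / 2 + 2 * hf, hf, hc = 4 * hf)
    ys <- sort(unique(round(c(ys_fine, y_out), 9)))
  } else {
    # open channel (verification case): uniform resolution across the width
    ys <- seq(-width_um / 2, width_um / 2,
              length.out = max(33L, 2L * ceiling(width_um / (2 * hf)) + 1L))
  }
  nx <- length(xs)
  ny <- length(ys)
  nodes <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  nid <- function(i, j) i + nx * (j - 1L)

  cells <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L))
  n00 <- nid(cells$i, cells$j)
  n10 <- nid(cells$i + 1L, cells$j)
  n01 <- nid(cells$i, cells$j + 1L)
  n11 <- nid(cells$i + 1L, cells$j + 1L)
  tris <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))

  cx <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
  cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
  # nodes inside (or exactly on) a pillar are no-slip walls; the grid has
  # exact lines on the gap edges, so the throat cross-section is resolved
  # sharply while the slanted faces are stair-cased at the local grid size
  solid_nodes <- if (pillars) {
    which(pillar_sdf(surface, nodes[, 1], nodes[, 2]) <= 1e-9)
  } else integer(0)
  node_solid <- logical(nrow(nodes))
  node_solid[solid_nodes] <- TRUE
  solid <- node_solid[tris[, 1]] & node_solid[tris[, 2]] &
    node_solid[tris[, 3]]

  inlet <- which(abs(nodes[, 1] - xs[1]) < 1e-9)
  outlet <- which(abs(nodes[, 1] - xs[nx]) < 1e-9)
  walls <- which(abs(abs(nodes[, 2]) - width_um / 2) < 1e-9)

  structure(
    list(geometry = geometry, surface = surface,
         nodes = nodes, triangles = tris, solid = solid,
         solid_nodes = solid_nodes,
         xs = xs, ys = ys, nx = nx, ny = ny,
         length_um = length_um, width_um = width_um,
         inlet = inlet, outlet = outlet, walls = walls,
         pillars = pillars, refine_um = hf),
    class = "flow_domain")
}

#' @export
print.flow_domain <- function(x, ...) {
  cat(sprintf(
    "<flow_domain> %g x %g um, %d nodes, %d triangles (%d solid), gap %.3g um\n",
    x$length_um, x$width_um, nrow(x$nodes), nrow(x$triangles),
    sum(x$solid), x$geometry$gap_um))
  invisible(x)
}

# P1 basis data per triangle: area and shape-function gradients
tri_basis <- function(nodes, tris) {
  x1 <- nodes[tris[, 1], 1]; y1 <- nodes[tris[, 1], 2]
  x2 <- nodes[tris[, 2], 1]; y2 <- nodes[tris[, 2], 2]
  x3 <- nodes[tris[, 3], 1]; y3 <- nodes[tris[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)   # 2*area, > 0
  list(area = a2 / 2,
       b = cbind((y2 - y3) / a2, (y3 - y1) / a2, (y1 - y2) / a2),
       c = cbind((x3 - x2) / a2, (x1 - x3) / a2, (x2 - x1) / a2))
}

#' Solve the carrier flow through a trapping unit
#'
#' Solves steady incompressible flow on a [flow_domain()] with stabilised
#' P1-P1 finite elements. Velocity is prescribed at the inlet from the flow
#' rate, the side walls are no-slip, and the outlet is traction-free (zero
#' reference pressure). Pillar interiors are excluded from the
#' discretisation and their stair-cased boundary nodes are no-slip; an
#' optional depth-averaged drag `12 mu / h^2 u` accounts for the top and
#' bottom channel walls. At device Reynolds numbers the convective term is
#' negligible; set `convective = TRUE` to include it via Picard iteration.
#'
#' @param domain A [flow_domain()].
#' @param conditions A [flow_conditions()].
#' @param depth_term Include the depth-averaged (Brinkman) drag for the
#'   finite channel height. Default TRUE.
#' @param convective Include the convective term (Picard iteration).
#'   Default FALSE (Stokes flow).
#' @param inlet_profile `"uniform"` (plug, default) or `"parabolic"`.
#'
#' @return An object of class `flow_solution`: nodal velocity (um/s) and
#'   pressure (Pa) fields, inlet/outlet fluxes, gap Reynolds number and
#'   solver metadata. Use [as_tibble()] / [autoplot()] to inspect.
#' @export
solve_flow <- function(domain, conditions, depth_term = TRUE,
                       convective = FALSE,
                       inlet_profile = c("uniform", "parabolic"),
                       stab_alpha = 0.05) {
  stopifnot(inherits(domain, "flow_domain"),
            inherits(conditions, "flow_conditions"))
  inlet_profile <- match.arg(inlet_profile)
  mu <- conditions$viscosity_pa_s
  h_ch <- conditions$channel_height_um
  W <- domain$width_um
  q_um3_s <- conditions$flow_rate_ul_min * 1e9 / 60
  u_mean <- q_um3_s / (W * h_ch)          # um/s

  nodes <- domain$nodes
  # fully-solid elements are removed from the discretisation: the staircase
  # pillar boundary becomes a true mesh boundary (no-slip node set), and
  # interior pillar dofs are pinned below
  tris <- domain$triangles[!domain$solid, , drop = FALSE]
  nv <- nrow(nodes)
  bas <- tri_basis(nodes, tris)
  A <- bas$area
  bb <- bas$b
  cc <- bas$c
  # longest edge squared per element (the tensor mesh is anisotropic where
  # the grading changes, so the stabilisation scales with the longest edge)
  e1 <- (nodes[tris[, 2], 1] - nodes[tris[, 1], 1])^2 +
    (nodes[tris[, 2], 2] - nodes[tris[, 1], 2])^2
  e2 <- (nodes[tris[, 3], 1] - nodes[tris[, 2], 1])^2 +
    (nodes[tris[, 3], 2] - nodes[tris[, 2], 2])^2
  e3 <- (nodes[tris[, 1], 1] - nodes[tris[, 3], 1])^2 +
    (nodes[tris[, 1], 2] - nodes[tris[, 3], 2])^2
  hmax2 <- pmax(e1, e2, e3)

  # drag coefficient per element: depth-averaged wall drag from the top and
  # bottom channel walls (the pillars themselves are no-slip node sets)
  sigma <- rep(if (depth_term) 12 * mu / h_ch^2 else 0, nrow(tris))
  supported <- logical(nv)
  supported[as.vector(tris)] <- TRUE

  idx_u <- function(k) k
  idx_v <- function(k) nv + k
  idx_p <- function(k) 2L * nv + k

  ii <- jj <- vv <- vector("list", 64L)
  slot <- 0L
  push <- function(i, j, v) {
    slot <<- slot + 1L
    ii[[slot]] <<- i; jj[[slot]] <<- j; vv[[slot]] <<- v
  }

  lump <- A / 3
  for (a in 1:3) {
    ta <- tris[, a]
    for (b in 1:3) {
      tb <- tris[, b]
      # viscous 2 mu eps(u):eps(v)
      push(idx_u(ta), idx_u(tb), mu * A * (2 * bb[, a] * bb[, b] + cc[, a] * cc[, b]))
      push(idx_u(ta), idx_v(tb), mu * A * (cc[, a] * bb[, b]))
      push(idx_v(ta), idx_u(tb), mu * A * (bb[, a] * cc[, b]))
      push(idx_v(ta), idx_v(tb), mu * A * (bb[, a] * bb[, b] + 2 * cc[, a] * cc[, b]))
      # pressure gradient (momentum): -int p div v
      push(idx_u(ta), idx_p(tb), -lump * bb[, a])
      push(idx_v(ta), idx_p(tb), -lump * cc[, a])
      # continuity: int q div u
      push(idx_p(ta), idx_u(tb), lump * bb[, b])
      push(idx_p(ta), idx_v(tb), lump * cc[, b])
      # pressure stabilisation (Brezzi-Pitkaranta): -delta grad q . grad p
      delta <- stab_alpha * hmax2 / mu
      push(idx_p(ta), idx_p(tb), -delta * A * (bb[, a] * bb[, b] + cc[, a] * cc[, b]))
    }
    # lumped drag
    push(idx_u(ta), idx_u(ta), sigma * lump)
    push(idx_v(ta), idx_v(ta), sigma * lump)
  }

  ndof <- 3L * nv
  base_trip <- list(i = unlist(ii[seq_len(slot)]), j = unlist(jj[seq_len(slot)]),
                    v = unlist(vv[seq_len(slot)]))

  # Dirichlet velocities
  yb <- nodes[domain$inlet, 2]
  u_in <- switch(inlet_profile,
                 uniform = rep(u_mean, length(yb)),
                 parabolic = 1.5 * u_mean * (1 - (2 * yb / W)^2))
  fixed0 <- union(domain$walls, domain$solid_nodes)
  unsupported <- which(!supported)
  dir_idx <- c(idx_u(domain$inlet), idx_v(domain$inlet),
               idx_u(fixed0), idx_v(fixed0), idx_p(unsupported))
  dir_val <- c(u_in, rep(0, length(domain$inlet) + 2 * length(fixed0) +
                           length(unsupported)))
  # walls win at shared corners
  corner <- intersect(domain$inlet, domain$walls)
  if (length(corner)) {
    dir_val[match(idx_u(corner), dir_idx)] <- 0
  }
  # normalise the discrete inlet profile so its trapezoidal flux equals the
  # requested flow rate exactly (corner zeroing and plug discretisation
  # would otherwise bias it by the wall-cell fraction)
  if (u_mean > 0) {
    yb_ord <- order(yb)
    uu <- dir_val[seq_along(domain$inlet)][yb_ord]
    q_disc <- sum(diff(yb[yb_ord]) * (head(uu, -1) + tail(uu, -1)) / 2)
    if (q_disc > 0) {
      scale_in <- (u_mean * W) / q_disc
      dir_val[seq_along(domain$inlet)] <-
        dir_val[seq_along(domain$inlet)] * scale_in
    }
  }

  solve_once <- function(extra = NULL) {
    trip <- base_trip
    if (!is.null(extra)) {
      trip <- list(i = c(trip$i, extra$i), j = c(trip$j, extra$j),
                   v = c(trip$v, extra$v))
    }
    keep <- !(trip$i %in% dir_idx)
    K <- Matrix::sparseMatrix(i = c(trip$i[keep], dir_idx),
                              j = c(trip$j[keep], dir_idx),
                              x = c(trip$v[keep], rep(1, length(dir_idx))),
                              dims = c(ndof, ndof))
    rhs <- numeric(ndof)
    rhs[dir_idx] <- dir_val
    as.numeric(Matrix::solve(K, rhs))
  }

  sol <- solve_once()
  n_picard <- 0L
  if (convective) {
    rho_um <- conditions$density_kg_m3 * 1e-15   # kg/um^3 -> Pa s^2/um^2
    for (it in 1:12) {
      u <- sol[1:nv]; v <- sol[nv + 1:nv]
      wx <- (u[tris[, 1]] + u[tris[, 2]] + u[tris[, 3]]) / 3
      wy <- (v[tris[, 1]] + v[tris[, 2]] + v[tris[, 3]]) / 3
      ei <- ej <- ev <- NULL
      for (a in 1:3) {
        for (b in 1:3) {
          val <- rho_um * lump * (wx * bb[, b] + wy * cc[, b])
          ei <- c(ei, idx_u(tris[, a]), idx_v(tris[, a]))
          ej <- c(ej, idx_u(tris[, b]), idx_v(tris[, b]))
          ev <- c(ev, val, val)
        }
      }
      new <- solve_once(list(i = ei, j = ej, v = ev))
      n_picard <- it
      if (max(abs(new - sol)) <= 1e-6 * max(abs(sol), 1e-12)) {
        sol <- new
        break
      }
      sol <- new
    }
  }

  u <- sol[1:nv]
  v <- sol[nv + 1:nv]
  p <- sol[2 * nv + 1:nv]

  flux_line <- function(node_ids) {
    yy <- nodes[node_ids, 2]
    ord <- order(yy)
    yy <- yy[ord]
    uu <- u[node_ids][ord]
    sum(diff(yy) * (head(uu, -1) + tail(uu, -1)) / 2)   # um^2/s per depth
  }
  q_in <- flux_line(domain$inlet) * h_ch
  q_out <- flux_line(domain$outlet) * h_ch

  g <- domain$geometry$gap_um
  u_gap <- q_um3_s / (g * h_ch)
  reynolds <- conditions$density_kg_m3 * (u_gap * 1e-6) * (g * 1e-6) / mu
  inform(sprintf("Gap Reynolds number: %.3g", reynolds),
         class = "pillartrap_message")

  structure(
    list(domain = domain, conditions = conditions,
         u = u, v = v, p = p,
         converged = TRUE, n_picard = n_picard,
         flux_in_um3_s = q_in, flux_out_um3_s = q_out,
         reynolds = reynolds,
         depth_term = depth_term, convective = convective,
         inlet_profile = inlet_profile),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> Q = %.3g uL/min, Re_gap = %.3g, flux balance %.3g%%, p range [%.4g, %.4g] Pa\n",
    x$conditions$flow_rate_ul_min, x$reynolds,
    100 * abs(x$flux_in_um3_s - x$flux_out_um3_s) /
      max(abs(x$flux_in_um3_s), 1e-300),
    min(x$p), max(x$p)))
  invisible(x)
}

#' @describeIn solve_flow Nodal fields as a tibble (x, y, u, v, p).
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @export
as_tibble.flow_solution <- function(x, ...) {
  out <- list(x = x$domain$nodes[, 1], y = x$domain$nodes[, 2],
              u_um_s = x$u, v_um_s = x$v, p_pa = x$p)
  tibble::new_tibble(out, nrow = length(out$x))
}

#' @describeIn solve_flow Pressure field and velocity magnitude plot.
#' @param object A `flow_solution`.
#' @export
autoplot.flow_solution <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$p_pa)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "p (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

# bilinear interpolation of a nodal field on the tensor grid
interp_field <- function(domain, field, px, py) {
  xs <- domain$xs
  ys <- domain$ys
  if (any(px < xs[1] - 1e-9 | px > xs[length(xs)] + 1e-9 |
            py < ys[1] - 1e-9 | py > ys[length(ys)] + 1e-9)) {
    pt_abort("Path exits the flow domain.", "invalid_input")
  }
  i <- pmin(pmax(findInterval(px, xs), 1L), length(xs) - 1L)
  j <- pmin(pmax(findInterval(py, ys), 1L), length(ys) - 1L)
  tx <- (px - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (py - ys[j]) / (ys[j + 1L] - ys[j])
  nid <- function(i, j) i + domain$nx * (j - 1L)
  f00 <- field[nid(i, j)]
  f10 <- field[nid(i + 1L, j)]
  f01 <- field[nid(i, j + 1L)]
  f11 <- field[nid(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

#' Pressure profile along a path through the gap
#'
#' Samples the pressure field along a polyline (by default the channel
#' centreline through the gap) and returns it against arc length. Through
#' the gap the pressure decreases monotonically in the flow direction; the
#' drop concentrates over the gap region.
#'
#' @param solution A `flow_solution` from [solve_flow()].
#' @param path Optional data frame with columns `x`, `y` (micrometres).
#'   Default: the centreline `y = 0` sampled at 200 points.
#' @param smooth_um Optional moving-average window (micrometres of arc
#'   length) applied to the sampled pressure. Nodal pressures from
#'   equal-order stabilised elements carry mesh-scale noise; a window of a
#'   few element sizes recovers the smooth profile.
#'
#' @return A tibble with `arc_length_um`, `x`, `y`, `pressure_pa`.
#' @export
pressure_along_gap <- function(solution, path = NULL, smooth_um = NULL) {
  stopifnot(inherits(solution, "flow_solution"))
  domain <- solution$domain
  if (is.null(path)) {
    L <- domain$length_um
    path <- tibble(x = seq(-L / 2, L / 2, length.out = 200), y = 0)
  }
  if (!all(c("x", "y") %in% names(path))) {
    pt_abort("`path` needs columns `x` and `y`.", "invalid_input")
  }
  p <- interp_field(domain, solution$p, path$x, path$y)
  arc <- c(0, cumsum(sqrt(diff(path$x)^2 + diff(path$y)^2)))
  if (!is.null(smooth_um)) {
    p <- vapply(seq_along(p), function(i) {
      mean(p[abs(arc - arc[i]) <= smooth_um / 2])
    }, numeric(1))
  }
  tibble(arc_length_um = arc, x = path$x, y = path$y, pressure_pa = p)
}

#' Mean pressure drop across the gap region
#'
#' Averages the pressure over short cross-segments spanning the open gap
#' just upstream and just downstream of the pillars and returns the
#' difference. This is the pressure magnitude suggested as the peak load
#' `P0` for the mechanical simulation ([parabolic_load()]).
#'
#' @param solution A `flow_solution`.
#' @return Pressure drop in Pa (positive for flow in +x).
#' @export
gap_mean_pressure <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  domain <- solution$domain
  g <- domain$geometry$gap_um
  x_off <- domain$surface$extent_x + 2
  ys <- seq(-0.45 * g, 0.45 * g, length.out = 9)
  p_up <- mean(interp_field(domain, solution$p, rep(-x_off, 9), ys))
  p_dn <- mean(interp_field(domain, solution$p, rep(x_off, 9), ys))
  p_up - p_dn
}

#' Velocity profile across the gap at the throat
#'
#' @param solution A `flow_solution`.
#' @param n Number of sample points across the open gap. Default 41.
#' @return A tibble with `y_um` and `u_um_s` (streamwise velocity at x = 0).
#' @export
gap_velocity_profile <- function(solution, n = 41) {
  stopifnot(inherits(solution, "flow_solution"))
  g <- solution$domain$geometry$gap_um
  ys <- seq(-g / 2, g / 2, length.out = n)
  tibble(y_um = ys,
         u_um_s = interp_field(solution$domain, solution$u, rep(0, n), ys))
}
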