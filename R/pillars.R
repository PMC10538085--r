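# Rigid diamond-pillar pair bounding one trapping unit.  The pillars are
# rhombic prisms with rounded (filleted) vertices; the pair is placed
# symmetrically about the flow axis (y = 0) so the facing rounded vertices
# are separated by exactly the requested gap, with the gap throat at x = 0.
#
# Contact queries use the exact signed distance of the rounded cross-section
# (distance to an inset rhombus minus the fillet radius); the triangulated
# facets are kept for inspection, export and clearance checks.

# Signed distance from 2D points to the rhombus with half-diagonals (a, b),
# centred at the origin (negative inside).  Vectorised.
sd_rhombus <- function(px, py, a, b) {
  qx <- abs(px)
  qy <- abs(py)
  # closest point on the segment (a,0)-(0,b)
  dx <- -a
  dy <- b
  t <- pmin(1, pmax(0, ((qx - a) * dx + qy * dy) / (dx * dx + dy * dy)))
  cx <- a + t * dx
  cy <- t * dy
  dist <- sqrt((qx - cx)^2 + (qy - cy)^2)
  inside <- qx / a + qy / b < 1
  ifelse(inside, -dist, dist)
}

#' Build the rigid pillar pair of a trapping unit
#'
#' Constructs the two diamond-prism pillars that bound one trapping gap.
#' Vertices are rounded with the fillet radius of the geometry, reproducing
#' the smoothness of moulded elastomer pillars, and the pillars are placed
#' so the minimum clearance between the facing rounded vertices equals the
#' gap exactly. The throat (narrowest cross-section) lies in the plane
#' `x = 0`, with the flow along +x.
#'
#' @param geometry A [trap_geometry()].
#' @param arc_segments Segments used to triangulate each fillet arc
#'   (representation only; contact uses the exact rounded cross-section).
#'
#' @return An object of class `rigid_surface` with the exact cross-section
#'   parameters (inset rhombus half-diagonals, fillet, pillar centre
#'   offset), the boundary polygon of one pillar in its local frame, and a
#'   triangulated facet list for both prisms.
#' @examples
#' build_pillar_surface(trap_geometry(8))
#' @export
build_pillar_surface <- function(geometry, arc_segments = 8) {
  stopifnot(inherits(geometry, "trap_geometry"))
  a <- geometry$diagonal_major_um / 2
  b <- geometry$diagonal_minor_um / 2
  rf <- geometry$fillet_radius_um
  h_apothem <- a * b / sqrt(a^2 + b^2)
  if (rf >= h_apothem) {
    pt_abort(sprintf(
      "Fillet radius %.3g um is too large for the diamond (max %.3g um).",
      rf, h_apothem), "invalid_geometry")
  }
  s <- (h_apothem - rf) / h_apothem
  a2 <- s * a
  b2 <- s * b
  apex_y <- b2 + rf                      # half-extent of the rounded pillar in y
  center_y <- geometry$gap_um / 2 + apex_y

  poly <- rounded_rhombus_polygon(a2, b2, rf, arc_segments)
  tris <- prism_triangles(poly, geometry$height_um, center_y)

  structure(
    list(geometry = geometry,
         inner_a = a2, inner_b = b2, fillet = rf,
         apex_y = apex_y, center_y = center_y,
         extent_x = a2 + rf,
         gap_throat_x = 0,
         polygon = poly, triangles = tris,
         height_um = geometry$height_um),
    class = "rigid_surface")
}

#' @export
print.rigid_surface <- function(x, ...) {
  cat(sprintf(
    "<rigid_surface> pillar pair: gap = %.3g um, half-extents %.3g x %.3g um, fillet %.3g um, %d facets\n",
    x$geometry$gap_um, x$extent_x, x$apex_y, x$fillet, nrow(x$triangles)))
  invisible(x)
}

# Boundary polygon (counter-clockwise, closed implicitly) of the rounded
# rhombus in its local frame: straight edge segments offset by rf from the
# inset rhombus, joined by fillet arcs centred at the inset vertices.  Each
# arc includes its angular midpoint, so the extreme points (e.g. the gap
# apex) are represented exactly.
rounded_rhombus_polygon <- function(a2, b2, rf, arc_segments = 8) {
  verts <- rbind(c(a2, 0), c(0, b2), c(-a2, 0), c(0, -b2))
  # outward normal direction (angle) of the edge from vertex i to i+1
  edge_normal <- function(p, q) {
    e <- q - p
    n <- c(e[2], -e[1])
    n / sqrt(sum(n^2))
  }
  pts <- NULL
  k <- max(2L, as.integer(arc_segments))
  for (i in 1:4) {
    p <- verts[i, ]
    q <- verts[if (i == 4) 1 else i + 1, ]
    pprev <- verts[if (i == 1) 4 else i - 1, ]
    n_in <- edge_normal(pprev, p)    # normal of edge arriving at vertex p
    n_out <- edge_normal(p, q)       # normal of edge leaving vertex p
    th1 <- atan2(n_in[2], n_in[1])
    th2 <- atan2(n_out[2], n_out[1])
    if (th2 < th1) th2 <- th2 + 2 * pi
    th <- seq(th1, th2, length.out = k + 1L)
    arc <- cbind(p[1] + rf * cos(th), p[2] + rf * sin(th))
    pts <- rbind(pts, arc)
  }
  # drop consecutive duplicates (rf = 0 collapses each arc to the vertex)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  pts[keep, , drop = FALSE]
}

# Triangulated facets (n x 9 matrix of coordinates: x1 y1 z1 x2 ...) of the
# two extruded pillars, mirrored about y = 0.
prism_triangles <- function(poly, height, center_y) {
  m <- nrow(poly)
  nxt <- c(2:m, 1L)
  one_pillar <- function(sign_y) {
    px <- poly[, 1]
    py <- sign_y * (poly[, 2] + center_y)
    side1 <- cbind(px, py, 0, px[nxt], py[nxt], 0, px[nxt], py[nxt], height)
    side2 <- cbind(px, py, 0, px[nxt], py[nxt], height, px, py, height)
    ctr <- c(mean(px), mean(py))
    cap_lo <- cbind(ctr[1], ctr[2], 0, px[nxt], py[nxt], 0, px, py, 0)
    cap_hi <- cbind(ctr[1], ctr[2], height, px, py, height,
                    px[nxt], py[nxt], height)
    rbind(side1, side2, cap_lo, cap_hi)
  }
  rbind(one_pillar(1), one_pillar(-1))
}

#' Signed distance from points to the pillar pair
#'
#' Exact signed distance (micrometres, negative inside a pillar) from 2D
#' points in the channel plane to the nearer of the two rounded pillars.
#' The out-of-plane coordinate is ignored: the pillars span the full channel
#' height.
#'
#' @param surface A `rigid_surface` from [build_pillar_surface()].
#' @param x,y Point coordinates, micrometres (vectorised).
#' @return Numeric vector of signed distances.
#' @examples
#' s <- build_pillar_surface(trap_geometry(8))
#' pillar_sdf(s, 0, 0)  # centre of the gap: half the gap width
#' @export
pillar_sdf <- function(surface, x, y) {
  stopifnot(inherits(surface, "rigid_surface"))
  ly <- abs(y) - surface$center_y
  sd_rhombus(x, ly, surface$inner_a, surface$inner_b) - surface$fillet
}

# Starting x-position for a cell of diameter a: tangent to the upstream
# faces of both pillars (centre on the flow axis).  Falls back to a position
# just upstream of the pillars when the cell fits through the gap freely.
initial_cell_x <- function(surface, diameter_um) {
  r <- diameter_um / 2
  gap <- surface$geometry$gap_um
  if (diameter_um <= gap) {
    return(-(surface$extent_x + 0.55 * diameter_um))
  }
  f <- function(x) pillar_sdf(surface, x, 0) - r
  lo <- -(surface$extent_x + diameter_um)
  uniroot(f, c(lo, 0), tol = 1e-10)$root
}

# Same, but tangency of the actual discrete surface (mesh nodes), leaving a
# small positive clearance so the initial state is contact-free.
initial_mesh_x <- function(surface, mesh) {
  d <- mesh$diameter_um
  if (d <= surface$geometry$gap_um) {
    return(-(surface$extent_x + 0.55 * d))
  }
  sn <- mesh$nodes[mesh$surf_nodes, , drop = FALSE]
  clear <- 1e-3 * mesh$h_edge
  f <- function(x0) min(pillar_sdf(surface, sn[, 1] + x0, sn[, 2])) - clear
  lo <- -(surface$extent_x + d)
  uniroot(f, c(lo, 0), tol = 1e-10)$root
}
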