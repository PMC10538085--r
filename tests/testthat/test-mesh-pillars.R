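# Sphere meshing and the rigid pillar pair.

test_that("sphere meshes are watertight with calibrated volume", {
  for (case in list(c(17, 4), c(17, 6), c(10, 5))) {
    m <- cell_mesh(case[1], case[2])
    expect_lt(abs(m$volume - pi * case[1]^3 / 6) / (pi * case[1]^3 / 6),
              0.01)
    expect_true(all(m$volumes > 0))
    # every tet face is shared by at most two tets, boundary faces once
    faces <- rbind(m$tets[, c(1, 2, 3)], m$tets[, c(1, 2, 4)],
                   m$tets[, c(1, 3, 4)], m$tets[, c(2, 3, 4)])
    key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
    counts <- table(key)
    expect_true(all(counts <= 2))
    expect_equal(sum(counts == 1), nrow(m$tris))
    # surface area close to the sphere's
    expect_lt(abs(sum(m$tri_areas) - pi * case[1]^2) / (pi * case[1]^2),
              0.06)
  }
})

test_that("mirror-symmetry index maps reflect node positions", {
  m <- cell_mesh(12, 4)
  expect_equal(m$nodes[m$mirror_y, 2], -m$nodes[, 2])
  expect_equal(m$nodes[m$mirror_y, c(1, 3)], m$nodes[, c(1, 3)])
  expect_equal(m$nodes[m$mirror_z, 3], -m$nodes[, 3])
})

test_that("pillar pair has exactly the requested clearance", {
  for (g in c(4, 8)) {
    for (rf in c(0, 2, 5)) {
      s <- build_pillar_surface(trap_geometry(g, fillet_radius_um = rf))
      # nearest-facet search between the two triangulated pillars
      tr <- s$triangles
      half <- nrow(tr) / 2
      v1 <- unique(rbind(tr[1:half, 1:3], tr[1:half, 4:6],
                         tr[1:half, 7:9]))
      v2 <- unique(rbind(tr[-(1:half), 1:3], tr[-(1:half), 4:6],
                         tr[-(1:half), 7:9]))
      dmin <- min(sqrt(outer(v1[, 1], v2[, 1], "-")^2 +
                         outer(v1[, 2], v2[, 2], "-")^2))
      expect_equal(dmin, g, tolerance = 1e-9)
      # the signed distance agrees: gap centre is g/2 from either pillar
      expect_equal(pillar_sdf(s, 0, 0), g / 2, tolerance = 1e-9)
    }
  }
})

test_that("pillar geometry errors are classed", {
  expect_error(build_pillar_surface(trap_geometry(8, fillet_radius_um = 30)),
               class = "pillartrap_error_invalid_geometry")
  expect_error(trap_geometry(75), class = "pillartrap_error_invalid_geometry")
})

test_that("signed distance is negative inside and matches geometry outside", {
  s <- build_pillar_surface(trap_geometry(8))
  expect_lt(pillar_sdf(s, 0, s$center_y), 0)       # pillar centre
  expect_lt(pillar_sdf(s, 0, -s$center_y), 0)      # mirrored pillar
  expect_equal(pillar_sdf(s, 0, 0), 4)
  far <- pillar_sdf(s, -100, 0)
  expect_gt(far, 50)
})
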