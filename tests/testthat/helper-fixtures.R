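# Shared fixtures: all built in code at test time.

# Noiseless dataset generated by the closed-form power law over a grid of
# moduli, diameters and gaps.
eq4_grid <- function(E = c(350, 430, 500, 650),
                     a = c(10, 15, 20, 25, 30),
                     g = c(4, 6, 8, 10),
                     coefficient = 0.027, exponent = 2) {
  tidyr::expand_grid(E_pa = E, diameter_um = a, gap_um = g) |>
    dplyr::mutate(nu = 0.3,
                  pc_pa = coefficient * E_pa *
                    (diameter_um / gap_um)^exponent)
}

# Coarse, fast solver settings for unit tests of the contact simulator.
fast_control <- function(...) sim_control(resolution = 4, ...)

# One small trapped-equilibrium outcome, computed once per test run.
trapped_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mesh <- cell_mesh(12, 4)
      cache <<- list(
        mesh = mesh,
        material = material_nh(430),
        surface = build_pillar_surface(trap_geometry(8)),
        outcome = simulate_passage(mesh, material_nh(430),
                                   build_pillar_surface(trap_geometry(8)),
                                   parabolic_load(30, 6),
                                   control = fast_control()))
    }
    cache
  }
})
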