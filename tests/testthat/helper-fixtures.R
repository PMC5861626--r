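# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_cohort <- function() {
  validate_cohort(data.frame(
    id = c("a1", "a2", "p1"),
    group = c("anterior", "anterior", "posterior"),
    diameter_mm = c(2.0, 1.4, 3.1),
    entry_angle_deg = c(95, 120, 40),
    stringsAsFactors = FALSE))
}

# converged plane-Poiseuille field: 8 mm channel, 32 cells across,
# parabolic inlet so the analytic profile holds along the whole channel
poiseuille_field <- function() {
  cached("poiseuille", {
    geom <- channel_geometry(width = 8, length = 40)
    mask <- rasterize(geom, 0.25)
    bc <- boundary_conditions(u_ss_inlet = 0.15, u_bv_inlet = 0,
                              inlet_profile = "parabolic")
    solve_steady(mask, bc, config = solver_config(tolerance = 1e-6))
  })
}

poiseuille_tau_ref <- function(U = 0.15, h_mm = 8, mu = 4.24e-3) {
  6 * mu * U / (h_mm * 1e-3)
}

# solver configuration used for desk-scale junction runs in the tests:
# shortened vessels, lattice Mach capped at 0.05 (the acute-corner jet is
# unstable at 0.1), convergence at 2e-4 -- the residual floor left by the
# weak corner oscillation sits near 1e-4 on some acute geometries
junction_test_config <- function(tolerance = 2e-4) {
  run_config(L_up = 12, L_down = 30, L_bv = 20, spacing_divisor = 8,
             solver = solver_config(tolerance = tolerance, u_lat_max = 0.05,
                                    max_iterations = 250000L))
}

# a constructed WSS profile (no solver): Gaussian dip on a plateau
synthetic_dip_profile <- function(base = 0.5, depth = 0.4, center = 5,
                                  width = 1, s = seq(0, 15, by = 0.05)) {
  tau <- base - depth * exp(-(s - center)^2 / (2 * width^2))
  structure(list(wall = "SSD", s = s, tau = tau,
                 included = rep(TRUE, length(s)), exclusions = list(),
                 geometry = NULL, spacing = s[2] - s[1]),
            class = "wss_profile")
}
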