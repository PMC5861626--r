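test_that("average WSS is the length-weighted mean of the profile", {
  pr <- synthetic_dip_profile(base = 0.5, depth = 0)   # constant 0.5
  expect_equal(average_wss(pr), 0.5)
  expect_equal(average_wss(pr, c(2, 9)), 0.5)
  # step profile: 0.4 on the first half, 0.6 on the second -> 0.5
  s <- seq(0, 10, by = 0.01)
  pr2 <- structure(list(wall = "SSD", s = s,
                        tau = ifelse(s < 5, 0.4, 0.6),
                        included = rep(TRUE, length(s)), exclusions = list(),
                        geometry = NULL, spacing = 0.01),
                   class = "wss_profile")
  expect_equal(average_wss(pr2), 0.5, tolerance = 2e-3)
  expect_error(average_wss(pr2, c(20, 30)), "overlap")
})

test_that("trapezoid and midpoint quadratures agree on smooth profiles", {
  s <- seq(0, 10, by = 0.05)
  tau <- 0.5 + 0.1 * sin(s)
  trap <- sum(diff(s) * (head(tau, -1) + tail(tau, -1)) / 2) / (max(s) - min(s))
  mids <- (head(s, -1) + tail(s, -1)) / 2
  midp <- mean(0.5 + 0.1 * sin(mids))
  pr <- structure(list(wall = "SSD", s = s, tau = tau,
                       included = rep(TRUE, length(s)), exclusions = list(),
                       geometry = NULL, spacing = 0.05),
                  class = "wss_profile")
  expect_equal(average_wss(pr), trap, tolerance = 1e-12)
  expect_equal(average_wss(pr) / midp, 1, tolerance = 0.01)
})

test_that("minimum location and value follow the analytic construction", {
  # tau(s) = 0.5 - 0.4 exp(-(s-5)^2/2): minimum 0.1 at s = 5
  pr <- synthetic_dip_profile(base = 0.5, depth = 0.4, center = 5, width = 1)
  mw <- min_wss(pr)
  expect_equal(mw$value, 0.1, tolerance = 1e-6)
  expect_equal(mw$position, 5, tolerance = 0.05 + 1e-9)

  # constant profile: tie broken toward the smallest |s|
  prc <- synthetic_dip_profile(depth = 0)
  expect_equal(min_wss(prc)$position, 0)
  expect_equal(min_wss(prc)$value, 0.5)
})

test_that("extent below a threshold matches the analytic dip width", {
  pr <- synthetic_dip_profile(base = 0.5, depth = 0.4, center = 5, width = 1)
  # tau < 0.3 on |s - 5| < sqrt(2 ln 2): full width 2.3548
  expect_equal(extent_below(pr, 0.3), 2 * sqrt(2 * log(2)),
               tolerance = pr$spacing * 2)
  expect_equal(extent_below(pr, 0.05), 0)     # never below
  expect_equal(extent_below(pr, 0.7), max(pr$s) - min(pr$s))  # all below
})

test_that("the plateau estimate ignores dips confined to excluded zones", {
  g <- build_geometry(d_bv = 3, alpha = 90, lengths = c(30, 60, 20))
  ssd <- wall_arclength(g, "SSD", step = 0.1)
  s <- ssd$s
  # dip entirely inside the entrance exclusion (1.5 mouth spans = 4.5 mm)
  tau <- 0.6 - 0.5 * exp(-(s - 1)^2 / 0.5)
  pr <- structure(list(wall = "SSD", s = s, tau = tau,
                       included = rep(TRUE, length(s)), exclusions = list(),
                       geometry = g, spacing = 0.1),
                  class = "wss_profile")
  st <- stable_value(pr, g)
  expect_equal(st$value, 0.6, tolerance = 1e-3)
  expect_gte(st$extent[1], 4.5)
  # a constant profile returns the constant with a nonempty window
  prc <- pr; prc$tau <- rep(0.42, length(s))
  stc <- stable_value(prc, g)
  expect_equal(stc$value, 0.42)
  expect_gt(diff(stc$extent), 0)
})

test_that("an empty plateau window raises a named analysis error", {
  g <- build_geometry(d_bv = 3, alpha = 90, lengths = c(30, 60, 20))
  ssd <- wall_arclength(g, "SSD", step = 0.1)
  pr <- structure(list(wall = "SSD", s = ssd$s,
                       tau = rep(0.5, nrow(ssd)),
                       included = rep(TRUE, nrow(ssd)), exclusions = list(),
                       geometry = g, spacing = 0.1),
                  class = "wss_profile")
  # entrance exclusion so wide it swallows the whole wall
  expect_error(stable_value(pr, g, entrance_spans = 60), "entrance exclusion")
})

test_that("Poiseuille wall shear matches the closed form within 2 percent", {
  f <- poiseuille_field()
  expect_true(f$converged)
  tau_ref <- poiseuille_tau_ref()
  for (w in c("lower", "upper")) {
    pr <- wall_shear_profile(f, w)
    mid <- abs(pr$s) < 10    # central stretch, away from inlet/outlet
    expect_equal(mean(pr$tau[mid]) / tau_ref, 1, tolerance = 0.02)
    expect_lt(max(abs(pr$tau[mid] / tau_ref - 1)), 0.02)
  }
  # centerline velocity is 1.5x the mean
  v <- velocity_at(f, 0, 4)
  expect_equal(v$ux / (1.5 * 0.15), 1, tolerance = 0.02)
  expect_lt(abs(v$uy), 1e-3 * 0.15)
})

test_that("a zero-velocity field has identically zero wall shear", {
  g <- channel_geometry(width = 8, length = 20)
  m <- rasterize(g, 0.5)
  f0 <- solve_steady(m, boundary_conditions(u_ss_inlet = 0, u_bv_inlet = 0))
  expect_true(f0$converged)
  pr <- wall_shear_profile(f0, "lower")
  expect_true(all(pr$tau == 0))
  expect_true(all(f0$pressure == 0))
})

test_that("on straight channels the minimum matches the plateau", {
  f <- poiseuille_field()
  pr <- wall_shear_profile(f, "lower")
  st <- stable_value(pr)
  mw <- min_wss(pr)
  expect_lte(mw$value, st$value + 1e-12)
  expect_gt(mw$value, 0.97 * st$value)   # no junction, no deficit
  # the minimum never exceeds the average over any containing interval
  expect_lte(mw$value, average_wss(pr, c(mw$s - 2, mw$s + 2)))
})

test_that("wall shear scales linearly with viscosity at fixed kinematics", {
  g <- channel_geometry(width = 8, length = 30)
  m <- rasterize(g, 0.5)
  bc <- boundary_conditions(u_ss_inlet = 0.05, u_bv_inlet = 0,
                            inlet_profile = "parabolic")
  cfg <- solver_config(tolerance = 1e-6)
  f1 <- solve_steady(m, bc, fluid_properties(viscosity = 4.24e-3), cfg)
  f2 <- solve_steady(m, bc, fluid_properties(viscosity = 8.48e-3), cfg)
  p1 <- wall_shear_profile(f1, "lower")
  p2 <- wall_shear_profile(f2, "lower")
  mid1 <- abs(p1$s) < 8; mid2 <- abs(p2$s) < 8
  expect_equal(mean(p2$tau[mid2]) / mean(p1$tau[mid1]), 2, tolerance = 0.02)
})
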