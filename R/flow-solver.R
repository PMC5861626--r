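#' Fluid properties
#'
#' Newtonian fluid constants; the defaults are normal blood treated as a
#' Newtonian fluid (density 1050 kg/m^3, dynamic viscosity 4.24e-3 Pa s).
#'
#' @param density fluid density, kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return List of class `"fluid_properties"`.
#' @export
fluid_properties <- function(density = 1050, viscosity = 4.24e-3) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions for the junction flow
#'
#' Velocity inlets on the sinus and the vein, a zero-gauge-pressure outlet
#' at the downstream sinus end, and no-slip walls. Defaults are venous
#' physiology: 15 cm/s into the superior sagittal sinus, 10 cm/s into the
#' bridging vein. The ambient (intracranial) pressure is an additive gauge
#' constant that cannot affect velocity or wall shear in incompressible
#' rigid-wall flow; it is carried as metadata only.
#'
#' @param u_ss_inlet mean SSS inlet velocity, m/s.
#' @param u_bv_inlet mean BV inlet velocity, m/s.
#' @param outlet_gauge_pressure outlet gauge pressure, Pa.
#' @param ambient_pressure ambient (intracranial) pressure, Pa; metadata only.
#' @param inlet_profile `"uniform"` (plug) or `"parabolic"` across each inlet.
#' @return List of class `"boundary_conditions"`.
#' @export
boundary_conditions <- function(u_ss_inlet = 0.15, u_bv_inlet = 0.10,
                                outlet_gauge_pressure = 0,
                                ambient_pressure = 1333,
                                inlet_profile = c("uniform", "parabolic")) {
  stopifnot(u_ss_inlet >= 0, u_bv_inlet >= 0)
  structure(list(u_ss_inlet = u_ss_inlet, u_bv_inlet = u_bv_inlet,
                 outlet_gauge_pressure = outlet_gauge_pressure,
                 ambient_pressure = ambient_pressure,
                 inlet_profile = match.arg(inlet_profile)),
            class = "boundary_conditions")
}

#' Solver configuration
#'
#' Numerical controls for the D2Q9 lattice Boltzmann scheme. The lattice
#' time step is set from the relaxation time where possible
#' (`tau_target`, diffusive scaling, so the lattice Mach number shrinks
#' linearly under grid refinement) but is capped so the reference lattice
#' velocity never exceeds `u_lat_max`; at venous Reynolds numbers on
#' desk-scale grids the cap binds and the relaxation time falls toward 0.5.
#' The default collision operator is the two-relaxation-time (TRT) one with
#' the odd-moment rate held at `omega_odd`: tying the odd rate to the
#' even one (BGK, `scheme = "lbm_bgk"`) or to a fixed magic parameter
#' under-relaxes the odd moments as tau approaches 0.5 and loses either
#' stability or accuracy there.
#'
#' @param scheme `"lbm_trt"` or `"lbm_bgk"`.
#' @param tolerance convergence tolerance: relative L2 change of the velocity
#'   field over `check_every` steps.
#' @param max_iterations step budget.
#' @param check_every residual diagnostic interval, steps.
#' @param u_lat_max lattice-velocity (Mach) cap.
#' @param tau_target preferred lattice relaxation time.
#' @param omega_odd TRT odd-moment relaxation rate, in (0, 2).
#' @param ramp_steps inlet velocities ramp linearly from zero over this many
#'   initial steps, avoiding the impulsive-start pressure transient.
#' @param seed recorded for provenance; the scheme is deterministic.
#' @return List of class `"solver_config"`.
#' @export
solver_config <- function(scheme = c("lbm_trt", "lbm_bgk"),
                          tolerance = 1e-6, max_iterations = 200000L,
                          check_every = 1000L, u_lat_max = 0.1,
                          tau_target = 0.55, omega_odd = 1.0,
                          ramp_steps = 2000L, seed = NULL) {
  stopifnot(tolerance > 0, max_iterations > 0, check_every > 0,
            u_lat_max > 0, u_lat_max < 0.3, tau_target > 0.5,
            omega_odd > 0, omega_odd < 2, ramp_steps >= 0)
  structure(list(scheme = match.arg(scheme), tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 check_every = as.integer(check_every),
                 u_lat_max = u_lat_max, tau_target = tau_target,
                 omega_odd = omega_odd, ramp_steps = as.integer(ramp_steps),
                 seed = seed),
            class = "solver_config")
}

#' Reynolds number
#'
#' `rho * U * d / mu` with the length scale given in millimetres.
#'
#' @param d characteristic length (vessel width), mm.
#' @param U characteristic velocity, m/s.
#' @param fluid a [fluid_properties()] object.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(d, U, fluid = fluid_properties()) {
  stopifnot(d >= 0, U >= 0)
  fluid$density * U * (d * 1e-3) / fluid$viscosity
}

#' Steady laminar flow in a rasterized junction
#'
#' Time-marches the D2Q9 lattice Boltzmann equation on the grid mask to a
#' steady state under the given boundary conditions, then converts back to
#' physical units. Walls use halfway bounce-back (no slip at the solid-fluid
#' cell interface), inlets impose the prescribed velocity profile through
#' local equilibrium distributions at streamed density, and the outlet
#' imposes the reference density (zero gauge pressure) with zero-gradient
#' velocity. Laminar regime is enforced by a Reynolds guard
#' (`Re < 2000` at both inlets).
#'
#' If both inlet velocities are zero the exact solution (zero velocity,
#' uniform gauge pressure) is returned directly.
#'
#' @param mask a [rasterize()] grid mask.
#' @param bc a [boundary_conditions()] object.
#' @param fluid a [fluid_properties()] object.
#' @param config a [solver_config()] object.
#' @return Object of class `"flow_field"`: velocity matrices `ux`, `uy`
#'   (m/s, zero in solid cells), gauge `pressure` (Pa), the `mask`,
#'   `converged` flag, `residual_history` data frame and a `meta` list with
#'   the lattice conversion factors.
#' @export
solve_steady <- function(mask, bc = boundary_conditions(),
                         fluid = fluid_properties(),
                         config = solver_config()) {
  stopifnot(inherits(mask, "grid_mask"))
  g <- mask$geometry
  re_ss <- reynolds_number(g$d_ss, bc$u_ss_inlet, fluid)
  re_bv <- reynolds_number(g$d_bv, bc$u_bv_inlet, fluid)
  if (max(re_ss, re_bv) >= 2000) {
    stop("regime error: inlet Reynolds number ", signif(max(re_ss, re_bv), 4),
         " is outside the laminar range (< 2000)")
  }
  h <- mask$spacing * 1e-3                 # m
  U_ref <- max(bc$u_ss_inlet, bc$u_bv_inlet)
  zero_mat <- function() matrix(0, mask$nx, mask$ny)
  if (U_ref == 0) {
    return(structure(list(
      spacing = mask$spacing, ux = zero_mat(), uy = zero_mat(),
      pressure = zero_mat() + bc$outlet_gauge_pressure, mask = mask,
      converged = TRUE, iterations = 0L,
      residual_history = data.frame(iteration = integer(), residual = numeric()),
      meta = list(dt = NA_real_, tau = NA_real_, u_lat_ref = 0,
                  scheme = config$scheme, reynolds = c(sss = 0, bv = 0),
                  fluid = fluid, bc = bc)),
      class = "flow_field"))
  }
  nu <- fluid$viscosity / fluid$density    # m^2/s
  nu_lat <- (config$tau_target - 0.5) / 3
  u_lat <- nu_lat * U_ref * h / nu
  if (u_lat > config$u_lat_max) {
    u_lat <- config$u_lat_max
    nu_lat <- u_lat * nu / (U_ref * h)
  }
  tau <- 3 * nu_lat + 0.5
  if (tau < 0.502) {
    stop("lattice relaxation time ", signif(tau, 6),
         " too close to 1/2; refine the grid (smaller spacing)")
  }
  dt <- u_lat * h / U_ref                  # s
  omega_plus <- 1 / tau
  omega_minus <- if (config$scheme == "lbm_bgk") omega_plus else
    config$omega_odd

  bc_cells <- mask$bc_cells
  speed <- ifelse(bc_cells$code == 2L, bc$u_ss_inlet,
                  ifelse(bc_cells$code == 3L, bc$u_bv_inlet, 0))
  shape <- if (bc$inlet_profile == "parabolic") {
    1.5 * (1 - pmin(abs(bc_cells$qn), 1)^2)
  } else rep(1, nrow(bc_cells))
  u_cell <- speed * shape * dt / h         # lattice units
  btype <- ifelse(bc_cells$code == 4L, 2L, 1L)
  nbr <- bc_anchor_cells(mask, bc_cells, btype)

  sol <- .lbm_solve(mask$cells,
                    as.integer(bc_cells$idx), as.integer(btype),
                    u_cell * bc_cells$dirx, u_cell * bc_cells$diry,
                    as.integer(nbr),
                    omega_plus, omega_minus,
                    config$max_iterations, config$check_every,
                    config$tolerance, config$ramp_steps)
  if (!sol$converged) {
    warning("flow solver did not reach tolerance ", config$tolerance,
            " within ", config$max_iterations, " steps (last residual ",
            signif(utils::tail(sol$residual, 1), 3), ")")
  }
  c_u <- h / dt                            # lattice -> m/s
  pressure <- (sol$rho - 1) / 3 * fluid$density * c_u^2 +
    bc$outlet_gauge_pressure
  pressure[mask$cells == 0L] <- NA_real_
  structure(list(
    spacing = mask$spacing, ux = sol$ux * c_u, uy = sol$uy * c_u,
    rho_lat = sol$rho,
    pressure = pressure, mask = mask,
    converged = sol$converged, iterations = sol$iterations,
    residual_history = data.frame(iteration = sol$res_iter,
                                  residual = sol$residual),
    meta = list(dt = dt, tau = tau, u_lat_ref = u_lat,
                omega_plus = omega_plus, omega_minus = omega_minus,
                scheme = config$scheme,
                reynolds = c(sss = re_ss, bv = re_bv),
                fluid = fluid, bc = bc)),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(paste0(
    "Steady flow field: %d x %d cells at %.4g mm spacing\n",
    "  %s, tau = %.4g, %d steps, converged: %s\n",
    "  max |u| = %.4g m/s\n"),
    nrow(x$ux), ncol(x$ux), x$spacing,
    x$meta$scheme, if (is.na(x$meta$tau)) 0 else x$meta$tau,
    x$iterations, x$converged,
    max(sqrt(x$ux^2 + x$uy^2))))
  invisible(x)
}

# For each boundary-condition cell, find the interior cell that anchors it:
# one to three steps along the inward lattice direction nearest the inflow
# (inlets) or the upstream direction (outlet), preferring a plain fluid cell.
bc_anchor_cells <- function(mask, bc_cells, btype) {
  nx <- mask$nx; ny <- mask$ny
  cells <- mask$cells
  inward_x <- ifelse(btype == 2L, -bc_cells$dirx, bc_cells$dirx)
  inward_y <- ifelse(btype == 2L, -bc_cells$diry, bc_cells$diry)
  exk <- c(1, 0, -1, 0, 1, -1, -1, 1)
  eyk <- c(0, 1, 0, -1, 1, 1, -1, -1)
  nrmk <- sqrt(exk^2 + eyk^2)
  vapply(seq_len(nrow(bc_cells)), function(m) {
    dots <- (inward_x[m] * exk + inward_y[m] * eyk) / nrmk
    k <- which.max(dots)
    ij <- arrayInd(bc_cells$idx[m], c(nx, ny))
    best <- 0L
    for (stp in 1:3) {
      i <- ij[1] + stp * exk[k]; j <- ij[2] + stp * eyk[k]
      if (i < 1 || i > nx || j < 1 || j > ny) break
      code <- cells[i, j]
      if (code == 0L) break
      best <- i + (j - 1L) * nx
      if (code == 1L) break
    }
    as.integer(best)
  }, integer(1))
}

#' Bilinear velocity interpolation
#'
#' Interpolates the velocity field at arbitrary points (mm coordinates).
#' With `fluid_only = TRUE` the bilinear weights are restricted to fluid
#' cells and renormalised, which avoids the spurious drag that staircase
#' solid cells (velocity zero, but lying beyond the true wall) would
#' otherwise exert on near-wall samples along oblique walls.
#'
#' @param field a [solve_steady()] flow field.
#' @param x,y point coordinates, mm (vectors of equal length).
#' @param fluid_only restrict the stencil to fluid cells?
#' @return List with vectors `ux`, `uy` (m/s).
#' @export
velocity_at <- function(field, x, y, fluid_only = FALSE) {
  h <- field$spacing
  ox <- field$mask$origin[1]; oy <- field$mask$origin[2]
  nx <- field$mask$nx; ny <- field$mask$ny
  # fractional cell-center index: fi = j exactly at the center of cell j
  fi <- (x - ox) / h + 0.5
  fj <- (y - oy) / h + 0.5
  i0 <- pmin(pmax(floor(fi), 1), nx - 1)
  j0 <- pmin(pmax(floor(fj), 1), ny - 1)
  wx <- pmin(pmax(fi - i0, 0), 1)
  wy <- pmin(pmax(fj - j0, 0), 1)
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy; w11 <- wx * wy
  if (fluid_only) {
    fl <- field$mask$cells > 0L
    w00 <- w00 * fl[cbind(i0, j0)]
    w10 <- w10 * fl[cbind(i0 + 1, j0)]
    w01 <- w01 * fl[cbind(i0, j0 + 1)]
    w11 <- w11 * fl[cbind(i0 + 1, j0 + 1)]
    wt <- w00 + w10 + w01 + w11
    wt[wt < 1e-3] <- 1   # fully-solid stencil: fall back to zero velocity
  } else {
    wt <- 1
  }
  bilin <- function(M) {
    (M[cbind(i0, j0)] * w00 + M[cbind(i0 + 1, j0)] * w10 +
       M[cbind(i0, j0 + 1)] * w01 + M[cbind(i0 + 1, j0 + 1)] * w11) / wt
  }
  list(ux = bilin(field$ux), uy = bilin(field$uy))
}

#' Global mass balance of a junction run
#'
#' Compares the outlet mass flux with the sum of the two inlet mass fluxes
#' (per unit depth; fluxes are density-weighted, since in the weakly
#' compressible lattice scheme the conserved quantity is rho u, not u).
#' The sinus fluxes are measured across interior cross-sections one cell
#' inside the boundary-condition layers (where the scheme's exact per-cell
#' mass conservation applies); the vein influx across a transverse section
#' at mid-vein.
#'
#' @param field a [solve_steady()] flow field on a junction mask.
#' @return List with `influx`, `outflux` (mm * m/s at reference density,
#'   per unit depth) and `rel_error` = |outflux - influx| / influx.
#' @export
mass_balance <- function(field) {
  mask <- field$mask; g <- mask$geometry; h <- mask$spacing
  rho <- field$rho_lat
  if (is.null(rho)) rho <- matrix(1, mask$nx, mask$ny)
  xc <- mask$origin[1] + (seq_len(mask$nx) - 0.5) * h
  yc <- mask$origin[2] + (seq_len(mask$ny) - 0.5) * h
  X <- matrix(xc, mask$nx, mask$ny)
  Y <- matrix(yc, mask$nx, mask$ny, byrow = TRUE)
  flux_x <- rho * field$ux * (mask$cells > 0L)
  in_sec <- X >= -g$L_up + h & X < -g$L_up + 2 * h & Y < g$d_ss
  out_sec <- X > g$L_down - 2 * h & X <= g$L_down - h & Y < g$d_ss
  influx_ss <- sum(flux_x[in_sec]) * h
  out <- sum(flux_x[out_sec]) * h
  t_ax <- (X - g$entrance[1]) * g$axis[1] + (Y - g$entrance[2]) * g$axis[2]
  band <- mask$cells > 0L & Y >= g$d_ss &
    abs((X - g$entrance[1]) * g$transverse[1] +
          (Y - g$entrance[2]) * g$transverse[2]) < g$d_bv / 2 &
    t_ax >= g$L_bv / 2 - h / 2 & t_ax < g$L_bv / 2 + h / 2
  influx_bv <- -sum((rho * (field$ux * g$axis[1] + field$uy * g$axis[2]))[band]) * h
  influx <- influx_ss + influx_bv
  list(influx = influx, outflux = out,
       influx_ss = influx_ss, influx_bv = influx_bv,
       rel_error = abs(out - influx) / max(abs(influx), .Machine$double.eps))
}
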