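#' Write legacy-VTK structured points
#'
#' Minimal ASCII writer for the legacy VTK STRUCTURED_POINTS format (2-D
#' grids written with a single z-slice), with any number of cell-centred
#' scalar fields and optional vector fields. Readable by ParaView and
#' pyvista/meshio.
#'
#' @param path output file path.
#' @param spacing grid spacing, mm.
#' @param origin grid origin (lower-left corner), mm.
#' @param scalars named list of numeric matrices (same dimensions).
#' @param vectors named list of `list(x = matrix, y = matrix)` pairs.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_structured_points <- function(path, spacing, origin,
                                        scalars = list(), vectors = list(),
                                        title = "bridgeflow field") {
  dims <- dim(if (length(scalars)) scalars[[1]] else vectors[[1]]$x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", dims[1], dims[2]),
               sprintf("ORIGIN %g %g 0", origin[1], origin[2]),
               sprintf("SPACING %g %g 1", spacing, spacing),
               sprintf("POINT_DATA %d", prod(dims))), con)
  fmt <- function(x) formatC(x, format = "g", digits = 8)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(fmt(as.vector(scalars[[nm]])), con)
  }
  for (nm in names(vectors)) {
    writeLines(sprintf("VECTORS %s float", nm), con)
    v <- vectors[[nm]]
    writeLines(paste(fmt(as.vector(v$x)), fmt(as.vector(v$y)), "0"), con)
  }
  invisible(path)
}

#' Export a grid mask as VTK plus a JSON sidecar
#'
#' Writes the cell classification (and wall labels) as integer scalar
#' fields and a JSON sidecar with the geometry parameters and wall anchor
#' coordinates.
#'
#' @param mask a [rasterize()] grid mask.
#' @param path output VTK path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
export_mask_vtk <- function(mask, path) {
  write_vtk_structured_points(
    path, mask$spacing, mask$origin + mask$spacing / 2,
    scalars = list(cell_class = mask$cells + 0,
                   wall_label = mask$wall_label + 0),
    title = "junction grid mask")
  g <- mask$geometry
  side <- list(
    d_ss = g$d_ss, d_bv = g$d_bv, alpha_deg = g$alpha,
    L_up = g$L_up, L_down = g$L_down, L_bv = g$L_bv,
    angle_convention = paste(
      "vein opens against the sinus stream: acute alpha = vein tube leaning",
      "downstream, discharging with an upstream (-x) component"),
    entrance = g$entrance, mouth_span = g$mouth_span,
    wall_anchors = lapply(g$walls, function(w) w$anchor),
    spacing = mask$spacing,
    cell_codes = c(solid = 0, fluid = 1, inlet_sss = 2, inlet_bv = 3,
                   outlet = 4))
  jsonlite::write_json(side, sub("\\.vtk$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a flow field as VTK plus a JSON sidecar
#'
#' Velocity (m/s) and gauge pressure (Pa) fields, plus JSON metadata with
#' unit conversions, convergence flag and residual history.
#'
#' @param field a [solve_steady()] flow field.
#' @param path output VTK path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
export_flow_vtk <- function(field, path) {
  p <- field$pressure
  p[is.na(p)] <- 0
  write_vtk_structured_points(
    path, field$spacing, field$mask$origin + field$spacing / 2,
    scalars = list(pressure_pa = p),
    vectors = list(velocity_ms = list(x = field$ux, y = field$uy)),
    title = "junction steady flow")
  meta <- list(
    units = list(length = "mm", velocity = "m/s", pressure = "Pa (gauge)"),
    spacing_mm = field$spacing, dt_s = field$meta$dt,
    tau = field$meta$tau, scheme = field$meta$scheme,
    u_lat_ref = field$meta$u_lat_ref,
    reynolds = as.list(field$meta$reynolds),
    ambient_pressure_pa = field$meta$bc$ambient_pressure,
    converged = field$converged, iterations = field$iterations,
    residual_history = field$residual_history)
  jsonlite::write_json(meta, sub("\\.vtk$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a WSS profile to CSV
#'
#' Columns `wall, s_mm, tau_pa, included`.
#'
#' @param profile a [wall_shear_profile()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wss_profile <- function(profile, path) {
  utils::write.csv(data.frame(wall = profile$wall, s_mm = profile$s,
                              tau_pa = profile$tau,
                              included = profile$included),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors [run_config()] with optional blocks `generator`
#' (seed, correlation, per-group overrides), `geometry`, `bc`, `fluid`,
#' `solver` and `analysis`; absent entries keep package defaults.
#'
#' @param path JSON file path.
#' @return List with `config` (a [run_config()]) and `generator`
#'   (seed/correlation/specs for [generate_cohort()]).
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  geo <- j$geometry %||% list()
  bcj <- j$bc %||% list()
  flj <- j$fluid %||% list()
  soj <- j$solver %||% list()
  anj <- j$analysis %||% list()
  cfg <- run_config(
    d_ss = geo$d_ss %||% 8, L_up = geo$L_up %||% 30,
    L_down = geo$L_down %||% 60, L_bv = geo$L_bv %||% 20,
    spacing = geo$spacing,
    spacing_divisor = geo$spacing_divisor %||% 10,
    spacing_cap = geo$spacing_cap %||% 0.25,
    bc = boundary_conditions(
      u_ss_inlet = bcj$u_ss_inlet %||% 0.15,
      u_bv_inlet = bcj$u_bv_inlet %||% 0.10,
      outlet_gauge_pressure = bcj$outlet_gauge_pressure %||% 0,
      ambient_pressure = bcj$ambient_pressure %||% 1333,
      inlet_profile = bcj$inlet_profile %||% "uniform"),
    fluid = fluid_properties(density = flj$density %||% 1050,
                             viscosity = flj$viscosity %||% 4.24e-3),
    solver = solver_config(
      scheme = soj$scheme %||% "lbm_trt",
      tolerance = soj$tolerance %||% 1e-6,
      max_iterations = soj$max_iterations %||% 200000L,
      check_every = soj$check_every %||% 1000L,
      u_lat_max = soj$u_lat_max %||% 0.1,
      tau_target = soj$tau_target %||% 0.55,
      omega_odd = soj$omega_odd %||% 1.0),
    inlet_widths = anj$inlet_widths %||% 2,
    entrance_spans = anj$entrance_spans %||% 1.5,
    diameter_floor = anj$diameter_floor %||% 1.2,
    angle_cutpoints = unlist(anj$angle_cutpoints %||% c(65, 105)),
    demarcation_min_ratio = anj$demarcation_min_ratio %||% 2)
  gen <- j$generator %||% list()
  specs <- default_group_specs()
  if (!is.null(gen$specs)) {
    for (nm in names(gen$specs)) {
      sp <- gen$specs[[nm]]
      base <- specs[[nm]]
      specs[[nm]] <- group_spec(
        group = nm, n = sp$n %||% base$n,
        diameter_mean = sp$diameter_mean %||% base$diameter_mean,
        diameter_sd = sp$diameter_sd %||% base$diameter_sd,
        diameter_bounds = unlist(sp$diameter_bounds %||% base$diameter_bounds),
        angle_mean = sp$angle_mean %||% base$angle_mean,
        angle_sd = sp$angle_sd %||% base$angle_sd,
        angle_bounds = unlist(sp$angle_bounds %||% base$angle_bounds))
    }
  }
  list(config = cfg,
       generator = list(seed = gen$seed %||% 1L,
                        correlation = gen$correlation %||% 0,
                        specs = specs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
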