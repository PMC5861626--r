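#' Run configuration for the model sweep
#'
#' Bundles the geometry defaults, boundary conditions, fluid, solver and
#' analysis settings that [run_sweep()] applies to every vein record. The
#' sinus caliber and vessel lengths are not anatomical measurements of this
#' cohort; they are explicit modelling assumptions (8 mm SSS width is a
#' literature-typical caliber; the downstream length accommodates minima
#' reported up to 50 mm from the entrance, the vein length minima up to
#' 13.5 mm). `spacing = NULL` applies the per-model rule
#' `min(d_bv / 10, spacing_cap)`.
#'
#' @param d_ss SSS channel width, mm.
#' @param L_up,L_down,L_bv vessel lengths, mm.
#' @param spacing grid spacing, mm, or `NULL` for the per-model rule.
#' @param spacing_cap cap of the per-model spacing rule, mm.
#' @param bc a [boundary_conditions()] object.
#' @param fluid a [fluid_properties()] object.
#' @param solver a [solver_config()] object.
#' @param inlet_widths,entrance_spans plateau exclusions, see [stable_value()].
#' @param diameter_floor diameter at or below which models are excluded from
#'   the grouped tables, mm.
#' @param angle_cutpoints the two entry-angle cutpoints of the three-bin
#'   grouping, degrees.
#' @param demarcation_min_ratio smallest adjacent ratio accepted as a
#'   demarcation by [demarcation_threshold()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(d_ss = 8, L_up = 30, L_down = 60, L_bv = 20,
                       spacing = NULL, spacing_divisor = 10,
                       spacing_cap = 0.25,
                       bc = boundary_conditions(),
                       fluid = fluid_properties(),
                       solver = solver_config(),
                       inlet_widths = 2, entrance_spans = 1.5,
                       diameter_floor = 1.2, angle_cutpoints = c(65, 105),
                       demarcation_min_ratio = 2) {
  stopifnot(d_ss > 0, L_up > 0, L_down > 0, L_bv > 0,
            is.null(spacing) || spacing > 0, spacing_divisor >= 8,
            length(angle_cutpoints) == 2,
            angle_cutpoints[1] < angle_cutpoints[2])
  structure(list(d_ss = d_ss, L_up = L_up, L_down = L_down, L_bv = L_bv,
                 spacing = spacing, spacing_divisor = spacing_divisor,
                 spacing_cap = spacing_cap,
                 bc = bc, fluid = fluid, solver = solver,
                 inlet_widths = inlet_widths, entrance_spans = entrance_spans,
                 diameter_floor = diameter_floor,
                 angle_cutpoints = angle_cutpoints,
                 demarcation_min_ratio = demarcation_min_ratio),
            class = "run_config")
}

model_spacing <- function(d_bv, config) {
  if (!is.null(config$spacing)) return(config$spacing)
  min(d_bv / (config$spacing_divisor %||% 10), config$spacing_cap)
}

#' Simulate and analyse one vein record
#'
#' Geometry, rasterization, steady flow solve and per-wall WSS analysis for
#' a single vein (diameter, entry angle). Per-wall plateau estimates that
#' have no valid window (degenerate geometries) are returned as `NA` rather
#' than failing the model.
#'
#' @param d_bv vein diameter, mm.
#' @param alpha entry angle, degrees.
#' @param config a [run_config()] object.
#' @param keep_field keep the full flow field in the result?
#' @return List with the geometry, convergence flag, and per-wall
#'   `stable` / `min` / `position` values (named by wall label); the flow
#'   field itself when `keep_field = TRUE`.
#' @export
run_model <- function(d_bv, alpha, config = run_config(), keep_field = FALSE) {
  geom <- build_geometry(d_ss = config$d_ss, d_bv = d_bv, alpha = alpha,
                         lengths = c(config$L_up, config$L_down, config$L_bv))
  mask <- rasterize(geom, model_spacing(d_bv, config))
  field <- solve_steady(mask, config$bc, config$fluid, config$solver)
  labs <- names(geom$walls)
  stable <- stats::setNames(rep(NA_real_, 6), labs)
  vmin <- stable; vpos <- stable
  profiles <- list()
  for (lb in labs) {
    pr <- wall_shear_profile(field, lb)
    profiles[[lb]] <- pr
    st <- tryCatch(stable_value(pr, geom, config$inlet_widths,
                                config$entrance_spans),
                   error = function(e) NULL)
    if (!is.null(st)) stable[lb] <- st$value
    mw <- tryCatch(min_wss(pr), error = function(e) NULL)
    if (!is.null(mw)) {
      vmin[lb] <- mw$value
      vpos[lb] <- mw$position
    }
  }
  out <- list(geometry = geom, converged = field$converged,
              stable = stable, min = vmin, position = vpos,
              profiles = profiles)
  if (keep_field) out$field <- field
  out
}

#' Sweep the junction model over a vein cohort
#'
#' Runs geometry -> solve -> WSS analysis for every record of a cohort and
#' collects the per-model minima, positions and plateau values that feed
#' the grouped minimum-WSS tables. Failures are recorded per model, never
#' silently dropped; the sweep is deterministic for a fixed cohort and
#' configuration.
#'
#' @param cohort a cohort data frame ([read_cohort()], [generate_cohort()]).
#' @param config a [run_config()] object.
#' @param verbose print per-model progress to stderr?
#' @return Object of class `"bv_sweep"`: `results` (one row per successful
#'   model: id, group, d_bv, alpha, converged, and `stable_*`, `min_*`,
#'   `pos_*` per wall), `failures` (id + message), and the `config`.
#' @export
run_sweep <- function(cohort, config = run_config(), verbose = FALSE) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop("empty cohort")
  rows <- list(); fails <- list()
  for (r in seq_len(nrow(cohort))) {
    rec <- cohort[r, ]
    if (verbose) {
      message(sprintf("[%d/%d] %s: d = %.2f mm, alpha = %.1f deg",
                      r, nrow(cohort), rec$id, rec$diameter_mm,
                      rec$entry_angle_deg))
    }
    res <- tryCatch(
      run_model(rec$diameter_mm, rec$entry_angle_deg, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        id = rec$id, message = conditionMessage(res),
        stringsAsFactors = FALSE)
      if (verbose) message("  failed: ", conditionMessage(res))
      next
    }
    row <- data.frame(id = rec$id, group = rec$group,
                      d_bv = rec$diameter_mm, alpha = rec$entry_angle_deg,
                      converged = res$converged, stringsAsFactors = FALSE)
    for (lb in names(res$stable)) {
      row[[paste0("stable_", lb)]] <- res$stable[[lb]]
      row[[paste0("min_", lb)]] <- res$min[[lb]]
      row[[paste0("pos_", lb)]] <- res$position[[lb]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    stop("sweep error: all ", nrow(cohort), " models failed; first failure: ",
         fails[[1]]$message)
  }
  structure(list(results = do.call(rbind, rows),
                 failures = if (length(fails)) do.call(rbind, fails) else
                   data.frame(id = character(), message = character()),
                 config = config),
            class = "bv_sweep")
}

#' @export
print.bv_sweep <- function(x, ...) {
  cat(sprintf("Junction model sweep: %d models (%d failed), %d converged\n",
              nrow(x$results) + nrow(x$failures), nrow(x$failures),
              sum(x$results$converged)))
  invisible(x)
}

#' Stratified representative subset of a cohort
#'
#' Picks the record nearest each (diameter bin x angle bin) cell centroid,
#' giving a small sweep that still spans the cohort's morphological range.
#'
#' @param cohort a cohort data frame.
#' @param d_breaks,a_breaks bin edges for diameter (mm) and angle (degrees).
#' @return Subset of `cohort` rows, at most one per occupied cell.
#' @export
stratified_subset <- function(cohort, d_breaks = c(0, 1.2, 2.5, 4, Inf),
                              a_breaks = c(0, 65, 105, 180)) {
  cohort <- validate_cohort(cohort)
  db <- cut(cohort$diameter_mm, d_breaks)
  ab <- cut(cohort$entry_angle_deg, a_breaks)
  pick <- unlist(lapply(split(seq_len(nrow(cohort)), interaction(db, ab, drop = TRUE)),
                        function(ix) {
                          d <- scale(cohort$diameter_mm[ix])[, 1]
                          a <- scale(cohort$entry_angle_deg[ix])[, 1]
                          d[is.na(d)] <- 0; a[is.na(a)] <- 0
                          ix[which.min(d^2 + a^2)]
                        }))
  out <- cohort[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reference 12-model subset
#'
#' The fixed diameter-by-angle grid (d in 1.0, 2.0, 3.0, 4.5 mm; alpha in
#' 43, 90, 135 degrees) used for qualitative trend checks: minima should
#' fall with growing diameter and with shrinking entry angle. Group labels
#' follow the anatomical association (shallow angles posterior, steep
#' anterior).
#'
#' @return A cohort data frame of 12 synthetic records.
#' @export
reference_subset <- function() {
  grid <- expand.grid(d = c(1.0, 2.0, 3.0, 4.5), a = c(43, 90, 135))
  validate_cohort(data.frame(
    id = sprintf("ref_d%.1f_a%d", grid$d, grid$a),
    group = ifelse(grid$a < 65, "posterior", "anterior"),
    diameter_mm = grid$d, entry_angle_deg = grid$a,
    stringsAsFactors = FALSE))
}

#' Demarcation threshold on sorted per-model minima
#'
#' Sorts the minima ascending and finds the adjacent pair with the largest
#' ratio; the demarcation is the geometric mean of that pair. The per-model
#' minima span orders of magnitude, so the "most drastic change of the
#' curve" is a ratio, not a difference. When no adjacent ratio reaches
#' `min_ratio` the result reports no demarcation rather than a number.
#'
#' @param minima numeric vector of per-model minimum WSS values, Pa (>= 3
#'   positive values).
#' @param min_ratio smallest adjacent ratio accepted as a demarcation.
#' @return List of class `"threshold_result"`: `found`,
#'   `wss_demarcation` (Pa, `NA` if not found), `pair` (the straddling
#'   values) and `ratio`.
#' @export
demarcation_threshold <- function(minima, min_ratio = 2) {
  minima <- minima[!is.na(minima)]
  if (length(minima) < 3L || any(minima <= 0)) {
    stop("need at least 3 positive minima")
  }
  v <- sort(minima)
  ratio <- v[-1] / v[-length(v)]
  i <- which.max(ratio)
  found <- ratio[i] >= min_ratio
  structure(list(found = found,
                 wss_demarcation = if (found) sqrt(v[i] * v[i + 1]) else NA_real_,
                 pair = c(v[i], v[i + 1]), ratio = ratio[i]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("WSS demarcation at %.4g Pa (between %.4g and %.4g, ratio %.3g)\n",
                x$wss_demarcation, x$pair[1], x$pair[2], x$ratio))
  } else {
    cat(sprintf("no demarcation (largest adjacent ratio %.3g)\n", x$ratio))
  }
  invisible(x)
}

summary_row <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(c(n = 0, mean = NA, sd = NA, min = NA, max = NA))
  }
  c(n = length(x), mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else 0, min = min(x), max = max(x))
}

group_metric_table <- function(results, grouping) {
  metrics <- c(min_SSD = "min_SSD", pos_SSD = "pos_SSD",
               min_BVU = "min_BVU", pos_BVU = "pos_BVU")
  rows <- list()
  for (gname in levels(grouping)) {
    sel <- !is.na(grouping) & grouping == gname
    for (m in names(metrics)) {
      st <- summary_row(results[[metrics[m]]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname,
        wall = sub("^(min|pos)_", "", m),
        metric = ifelse(grepl("^min", m), "min_value_pa", "position_mm"),
        n = st["n"], mean = st["mean"], sd = st["sd"],
        min = st["min"], max = st["max"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

group_anova <- function(results, grouping) {
  out <- list()
  for (m in c("min_SSD", "pos_SSD", "min_BVU", "pos_BVU")) {
    vals <- split(results[[m]][!is.na(grouping)], grouping[!is.na(grouping)])
    vals <- lapply(vals, function(v) v[!is.na(v)])
    vals <- vals[vapply(vals, length, 1L) >= 2L]
    out[[m]] <- if (length(vals) >= 2L && !all(vapply(vals, stats::var, 1) == 0)) {
      anova_oneway(vals)
    } else {
      list(F = NA_real_, p = NA_real_, df1 = NA_real_, df2 = NA_real_)
    }
  }
  out
}

#' Minimum-WSS table by entry-angle group
#'
#' Bins the sweep results into the three entry-angle groups (left-closed
#' bins, defaults `[10, 65)`, `[65, 105)`, `[105, 170]`, so that a vein
#' entering at exactly 65 degrees counts as steep -- angles at or above 65
#' degrees do not depress the vein-wall WSS), after removing veins with
#' diameter at or below the floor (default 1.2 mm -- thin veins do not
#' depress the WSS regardless of angle). Summarises the minimum WSS
#' value and its distance to the dural entrance for the downstream sinus
#' wall (SSD) and upstream vein wall (BVU), with a one-way ANOVA across
#' bins per metric.
#'
#' @param sweep a [run_sweep()] result (or its `results` data frame).
#' @param diameter_floor exclusion diameter, mm.
#' @param cutpoints the two angle cutpoints, degrees.
#' @return List of class `"group_table"`: `table` (per-bin summaries),
#'   `anova` (per metric), `n_excluded`, and the binning used.
#' @export
classify_angle_groups <- function(sweep, diameter_floor = 1.2,
                                  cutpoints = c(65, 105)) {
  results <- if (inherits(sweep, "bv_sweep")) sweep$results else sweep
  stopifnot(cutpoints[1] < cutpoints[2])
  keep <- results$d_bv > diameter_floor
  res <- results[keep, , drop = FALSE]
  breaks <- c(0, cutpoints, 180)
  labels <- sprintf("[%g,%g)", breaks[-4], breaks[-1])
  grouping <- cut(res$alpha, breaks = breaks, labels = labels, right = FALSE)
  structure(list(table = group_metric_table(res, grouping),
                 anova = group_anova(res, grouping),
                 n_excluded = sum(!keep), breaks = breaks,
                 by = "entry_angle"),
            class = "group_table")
}

#' Minimum-WSS comparison between anterior and posterior groups
#'
#' Per-group summaries of the minimum WSS value and its position for the
#' SSD and BVU walls, with the two-group one-way ANOVA per metric.
#'
#' @param sweep a [run_sweep()] result (or its `results` data frame).
#' @return List of class `"group_table"` as in [classify_angle_groups()].
#' @export
compare_anterior_posterior <- function(sweep) {
  results <- if (inherits(sweep, "bv_sweep")) sweep$results else sweep
  if (!all(c("anterior", "posterior") %in% results$group)) {
    stop("input error: both anterior and posterior groups are required")
  }
  grouping <- factor(results$group, levels = c("anterior", "posterior"))
  structure(list(table = group_metric_table(results, grouping),
                 anova = group_anova(results, grouping),
                 n_excluded = 0L, by = "segment_group"),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  cat("Minimum-WSS table by", x$by, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Percentage ratio
#'
#' `100 * numerator / denominator`, rounded half-up to an integer percent
#' (the printed convention of the result tables); `raw = TRUE` skips the
#' rounding.
#'
#' @param numerator,denominator numeric scalars, `denominator > 0`.
#' @param raw return the unrounded percentage?
#' @return Percentage.
#' @export
ratio_percent <- function(numerator, denominator, raw = FALSE) {
  if (!is.finite(denominator) || denominator <= 0) {
    stop("input error: denominator must be positive")
  }
  pct <- 100 * numerator / denominator
  if (raw) pct else floor(pct + 0.5)
}

#' Predilection extent of the low-WSS region
#'
#' The minimum sits near the centre of its depressed-WSS region, so the
#' region extends to about twice the largest observed minimum-to-entrance
#' distance.
#'
#' @param positions distances of per-model minima from the dural
#'   entrance, mm.
#' @return `2 * max(positions)`, mm.
#' @export
predilection_extent <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (length(positions) == 0L) stop("no positions supplied")
  2 * max(positions)
}
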