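#' Wall shear stress profile along a labelled wall
#'
#' Evaluates `tau(s) = mu * |du_t/dn|` at points spaced one grid cell apart
#' along the wall, where `u_t` is the velocity component tangent to the wall
#' and `n` the inward normal. The normal derivative at the wall uses a
#' one-sided second-order stencil through the no-slip wall value and two
#' interpolated samples at `h/2` and `3h/2` into the fluid (exact for
#' velocity profiles quadratic in the wall distance, so plane Poiseuille
#' flow is differentiated without truncation error). Points within two grid
#' spacings of the wall end that abuts an inlet or outlet face are marked
#' excluded.
#'
#' Walls running oblique to the grid are rasterized as staircases, which
#' leaves sample-to-sample noise in the extracted stress; their profiles are
#' smoothed with a short running mean (`smooth_window` points, default 5)
#' before analysis. Grid-aligned walls are left untouched.
#'
#' @param field a [solve_steady()] flow field.
#' @param wall a wall label string, or a [wall_arclength()] polyline taken
#'   from the same geometry the field was solved on.
#' @param smooth_window running-mean width (odd number of points) applied to
#'   oblique walls.
#' @return Object of class `"wss_profile"`: vectors `s` (arc length, mm,
#'   0 at the wall's junction anchor), `tau` (Pa), logical `included`,
#'   `exclusions` (list of s-intervals), and the wall label.
#' @export
wall_shear_profile <- function(field, wall, smooth_window = 5L) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$mask$geometry
  if (is.character(wall)) wall <- wall_arclength(g, wall, step = field$spacing)
  lab <- attr(wall, "label")
  tangent <- attr(wall, "tangent"); normal <- attr(wall, "normal")
  if (is.null(lab) || is.null(tangent)) {
    stop("input error: wall must be a label or a wall_arclength() polyline")
  }
  h <- field$spacing
  # grid-aligned walls: samples at h/2 and 3h/2 land on cell-center rows;
  # oblique (staircase) walls: step out to h and 2h and restrict the
  # interpolation stencil to fluid cells
  aligned <- max(abs(normal)) > 1 - 1e-9
  if (aligned) {
    a1 <- h / 2; a2 <- 3 * h / 2
  } else {
    a1 <- h; a2 <- 2 * h
  }
  p1 <- velocity_at(field, wall$x + a1 * normal[1], wall$y + a1 * normal[2],
                    fluid_only = !aligned)
  p2 <- velocity_at(field, wall$x + a2 * normal[1], wall$y + a2 * normal[2],
                    fluid_only = !aligned)
  f1 <- p1$ux * tangent[1] + p1$uy * tangent[2]
  f2 <- p2$ux * tangent[1] + p2$uy * tangent[2]
  # quadratic through (0, 0), (a1, f1), (a2, f2); distances in metres
  dudn <- (a2^2 * f1 - a1^2 * f2) / (a1 * a2 * (a2 - a1)) / 1e-3
  tau <- field$meta$fluid$viscosity * abs(dudn)
  if (!aligned && smooth_window > 1L && length(tau) > smooth_window) {
    kw <- as.integer(smooth_window) %/% 2L
    padded <- c(rep(tau[1], kw), tau, rep(tau[length(tau)], kw))
    tau <- as.numeric(stats::filter(padded, rep(1 / (2 * kw + 1), 2 * kw + 1),
                                    sides = 2))[(kw + 1):(kw + length(tau))]
  }
  s <- wall$s
  exclusions <- list()
  open_end <- attr(wall, "open_end")
  if (identical(open_end, "from") || identical(open_end, "both")) {
    exclusions <- c(exclusions, list(c(min(s), min(s) + 2 * h)))
  }
  if (identical(open_end, "to") || identical(open_end, "both")) {
    exclusions <- c(exclusions, list(c(max(s) - 2 * h, max(s))))
  }
  included <- rep(TRUE, length(s))
  for (ex in exclusions) included <- included & !(s >= ex[1] & s <= ex[2])
  structure(list(wall = lab, s = s, tau = tau, included = included,
                 exclusions = exclusions,
                 geometry = g, spacing = h),
            class = "wss_profile")
}

#' @export
print.wss_profile <- function(x, ...) {
  cat(sprintf("WSS profile on %s: %d points, s in [%.3g, %.3g] mm, tau in [%.4g, %.4g] Pa\n",
              x$wall, length(x$s), min(x$s), max(x$s), min(x$tau), max(x$tau)))
  invisible(x)
}

#' Length-weighted average WSS over an interval
#'
#' Discretises the normalised wall integral of the shear stress,
#' `avg = int tau ds / int ds`, over the part of the profile inside the
#' interval (trapezoidal rule; for a single surviving point, that point's
#' value).
#'
#' @param profile a [wall_shear_profile()] object.
#' @param interval numeric `c(s_lo, s_hi)`.
#' @return The average WSS, Pa.
#' @export
average_wss <- function(profile, interval = range(profile$s)) {
  stopifnot(inherits(profile, "wss_profile"), length(interval) == 2)
  keep <- profile$s >= interval[1] & profile$s <= interval[2]
  if (!any(keep)) stop("input error: interval does not overlap the profile")
  s <- profile$s[keep]; tau <- profile$tau[keep]
  if (length(s) == 1L) return(tau)
  sum(diff(s) * (utils::head(tau, -1) + utils::tail(tau, -1)) / 2) / (max(s) - min(s))
}

#' Plateau (stable) WSS of a wall
#'
#' The WSS along each wall is flat away from the vessel inlets and the
#' junction; this estimates that plateau as the median of `tau` after
#' excluding (a) points within `inlet_widths` local channel widths of the
#' wall's own vessel inlet, (b) points within `entrance_spans` vein-mouth
#' spans of the dural entrance, and (c) the profile's own inlet/outlet edge
#' exclusions. The median makes the estimate robust to any residual
#' junction tail inside the window.
#'
#' @param profile a [wall_shear_profile()] object.
#' @param geometry the [build_geometry()] the profile was computed on
#'   (defaults to the geometry recorded in the profile).
#' @param inlet_widths inlet exclusion, in local channel widths.
#' @param entrance_spans entrance exclusion, in vein-mouth spans.
#' @return List of class `"stable_value"`: `wall`, `value` (Pa), `extent`
#'   (s-range actually used) and `n` points.
#' @export
stable_value <- function(profile, geometry = profile$geometry,
                         inlet_widths = 2, entrance_spans = 1.5) {
  stopifnot(inherits(profile, "wss_profile"))
  g <- geometry
  s <- profile$s
  keep <- profile$included
  is_bv <- profile$wall %in% c("BVU", "BVD")
  width <- if (is_bv) g$d_bv else g$d_ss
  # distance of each wall point from its own vessel inlet, along the wall
  dist_inlet <- if (is_bv) {
    attr_len <- g$walls[[profile$wall]]$s_to
    attr_len - s
  } else {
    # SSS walls: x-coordinate relative to the sinus inlet at -L_up
    anchor_x <- g$walls[[profile$wall]]$anchor[1]
    (s + anchor_x) + g$L_up
  }
  keep_a <- dist_inlet >= inlet_widths * width
  keep_b <- abs(s) >= entrance_spans * g$mouth_span
  keep_all <- keep & keep_a & keep_b & is.finite(profile$tau)
  if (!any(keep_all)) {
    culprit <- if (!any(keep & keep_a)) {
      sprintf("inlet exclusion (%g local channel widths)", inlet_widths)
    } else {
      sprintf("entrance exclusion (%g vein-mouth spans)", entrance_spans)
    }
    stop("analysis error: empty plateau window on ", profile$wall,
         " after the ", culprit)
  }
  structure(list(wall = profile$wall,
                 value = stats::median(profile$tau[keep_all]),
                 extent = range(s[keep_all]), n = sum(keep_all)),
            class = "stable_value")
}

#' Minimum WSS and its distance from the dural entrance
#'
#' Global minimum of `tau` over the included points of the profile (only
#' the inlet/outlet edges are excluded -- the junction region is retained,
#' since that is where the minima live). Ties are broken toward the
#' smallest `|s|`; the reported position is `|s|`, the unsigned arc-length
#' distance from the wall's dural-entrance anchor.
#'
#' @param profile a [wall_shear_profile()] object.
#' @return List of class `"min_wss"`: `wall`, `value` (Pa), `position` (mm)
#'   and the signed `s` of the minimum.
#' @export
min_wss <- function(profile) {
  stopifnot(inherits(profile, "wss_profile"))
  keep <- which(profile$included & is.finite(profile$tau))
  if (length(keep) == 0L) {
    stop("analysis error: no included finite profile points")
  }
  tau <- profile$tau[keep]; s <- profile$s[keep]
  vmin <- min(tau)
  at <- keep[which(tau <= vmin + 1e-12 * max(vmin, 1))]
  smin <- profile$s[at]
  best <- at[which.min(abs(smin))]
  structure(list(wall = profile$wall, value = vmin,
                 position = abs(profile$s[best]), s = profile$s[best]),
            class = "min_wss")
}

#' Extent of the WSS deficit below a threshold
#'
#' Length of the maximal contiguous arc-length interval, containing the
#' profile minimum, over which `tau < threshold`. Returns 0 when the
#' minimum itself is not below the threshold.
#'
#' @param profile a [wall_shear_profile()] object.
#' @param threshold WSS threshold, Pa (> 0).
#' @return Interval length, mm.
#' @export
extent_below <- function(profile, threshold) {
  stopifnot(inherits(profile, "wss_profile"), threshold > 0)
  keep <- which(profile$included)
  if (length(keep) == 0L) return(0)
  s <- profile$s[keep]; tau <- profile$tau[keep]
  imin <- which.min(tau)
  if (tau[imin] >= threshold) return(0)
  lo <- imin
  while (lo > 1L && tau[lo - 1L] < threshold) lo <- lo - 1L
  hi <- imin
  while (hi < length(tau) && tau[hi + 1L] < threshold) hi <- hi + 1L
  s[hi] - s[lo]
}
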