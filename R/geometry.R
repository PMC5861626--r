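#' Parametric bridging vein-sinus junction geometry
#'
#' Builds the planar (symmetry-plane) model of one bridging vein (BV)
#' entering the superior sagittal sinus (SSS). The SSS is a straight channel
#' of width `d_ss` along the x-axis (flow in +x), occupying
#' `y in [0, d_ss]`, `x in [-L_up, L_down]`. The BV is a straight channel of
#' width `d_bv` whose centerline meets the upper SSS wall at the dural
#' entrance `(0, d_ss)`. The entry angle `alpha` is measured between the
#' vein and the sinus axis with the anatomical orientation of bridging
#' veins: they open against the sinus stream, so `alpha < 90` means the
#' vein tube leans downstream and discharges with an upstream-pointing
#' component (an opposing jet). At `alpha = 43` degrees (the posterior
#' group mean) the jet meets the sinus flow head-on in the acute wedge
#' between the downstream sinus wall and the vein wall -- the dead-water
#' zone where the wall shear deficit develops.
#'
#' Six wall segments are labelled (nomenclature of the junction walls):
#' `SSU`/`SSD` the upper SSS wall upstream/downstream of the vein mouth,
#' `SSO_U`/`SSO_D` the opposite (lower) SSS wall split at the foot of the
#' perpendicular from the entrance, and `BVU`/`BVD` the vein walls on the
#' upstream and downstream side of the mouth: `BVU` shares the upstream
#' junction corner with `SSU`, `BVD` the downstream corner with `SSD`. For
#' an acute (opposing) entry the vein outflow hugs `BVD` while `BVU`
#' borders the near-stagnant pocket at the mouth -- the wall the thrombosis
#' analysis singles out. The vein mouth spans `d_bv / sin(alpha)` along the
#' upper wall.
#'
#' @param d_ss SSS channel width, mm.
#' @param d_bv BV channel width, mm.
#' @param alpha entry angle, degrees, strictly inside (0, 180).
#' @param lengths named or positional numeric vector `(L_up, L_down, L_bv)`:
#'   SSS length upstream/downstream of the entrance and BV length, mm.
#' @return Object of class `"junction_geometry"`: the parameters, the
#'   `entrance` point, per-wall endpoints/anchors and the junction corner
#'   coordinates.
#' @export
build_geometry <- function(d_ss = 8, d_bv = 3, alpha = 90,
                           lengths = c(L_up = 30, L_down = 60, L_bv = 20)) {
  L_up <- lengths[[1]]; L_down <- lengths[[2]]; L_bv <- lengths[[3]]
  if (!(d_ss > 0 && d_bv > 0 && L_up > 0 && L_down > 0 && L_bv > 0)) {
    stop("geometry error: all widths and lengths must be positive")
  }
  if (!(alpha > 0 && alpha < 180)) {
    stop("geometry error: entry angle must lie strictly within (0, 180) degrees")
  }
  # internal angle of the vein axis against +x: the vein opens against the
  # stream, so the tube of an acute-alpha vein leans downstream
  a <- pi - alpha * pi / 180
  half_span <- d_bv / (2 * sin(a))       # corner offset along the upper wall
  if (half_span >= L_down) {
    stop("geometry error: BV mouth extends past the downstream SSS end ",
         "(d_bv/(2 sin(alpha)) = ", signif(half_span, 4), " >= L_down)")
  }
  if (half_span >= L_up) {
    stop("geometry error: BV mouth extends past the upstream SSS end ",
         "(d_bv/(2 sin(alpha)) = ", signif(half_span, 4), " >= L_up)")
  }
  u <- c(-cos(a), sin(a))   # BV axis, entrance -> BV inlet
  nrm <- c(sin(a), cos(a))  # BV transverse direction (+ side = downstream corner)
  ent <- c(0, d_ss)
  corner_d <- c(half_span, d_ss)     # downstream corner (SSD / BVU)
  corner_u <- c(-half_span, d_ss)    # upstream corner (SSU / BVD)
  # BV wall lengths from corner to the inlet face (perpendicular at L_bv)
  len_bvd <- L_bv + (d_bv / 2) / tan(a)
  len_bvu <- L_bv - (d_bv / 2) / tan(a)
  if (min(len_bvu, len_bvd) <= 0) {
    stop("geometry error: BV too short for its mouth ",
         "(need L_bv > d_bv/2 * |cot(alpha)|)")
  }
  walls <- list(
    SSU   = list(from = c(-L_up, d_ss), to = corner_u, anchor = corner_u,
                 tangent = c(1, 0), normal = c(0, -1),
                 s_from = -(L_up - half_span), s_to = 0, open_end = "from"),
    SSD   = list(from = corner_d, to = c(L_down, d_ss), anchor = corner_d,
                 tangent = c(1, 0), normal = c(0, -1),
                 s_from = 0, s_to = L_down - half_span, open_end = "to"),
    SSO_U = list(from = c(-L_up, 0), to = c(0, 0), anchor = c(0, 0),
                 tangent = c(1, 0), normal = c(0, 1),
                 s_from = -L_up, s_to = 0, open_end = "from"),
    SSO_D = list(from = c(0, 0), to = c(L_down, 0), anchor = c(0, 0),
                 tangent = c(1, 0), normal = c(0, 1),
                 s_from = 0, s_to = L_down, open_end = "to"),
    BVU   = list(from = corner_u, to = ent + L_bv * u - (d_bv / 2) * nrm,
                 anchor = corner_u, tangent = u, normal = nrm,
                 s_from = 0, s_to = len_bvu, open_end = "to"),
    BVD   = list(from = corner_d, to = ent + L_bv * u + (d_bv / 2) * nrm,
                 anchor = corner_d, tangent = u, normal = -nrm,
                 s_from = 0, s_to = len_bvd, open_end = "to")
  )
  structure(list(d_ss = d_ss, d_bv = d_bv, alpha = alpha,
                 L_up = L_up, L_down = L_down, L_bv = L_bv,
                 entrance = ent, axis = u, transverse = nrm,
                 mouth_span = 2 * half_span,
                 corner_down = corner_d, corner_up = corner_u,
                 walls = walls),
            class = "junction_geometry")
}

#' @export
print.junction_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "Bridging vein-SSS junction (planar)\n",
    "  SSS width %.3g mm, [-%g, %g] mm about the dural entrance\n",
    "  BV width %.3g mm, length %g mm, entry angle %.4g deg\n",
    "  vein mouth span on upper wall: %.4g mm\n"),
    x$d_ss, x$L_up, x$L_down, x$d_bv, x$L_bv, x$alpha, x$mouth_span))
  invisible(x)
}

#' Wall polyline with arc-length coordinates
#'
#' Returns one labelled wall as points with an arc-length coordinate `s`
#' anchored at the wall's junction (dural-entrance side) end: `s = 0` at the
#' anchor. For the SSS walls `s` increases in the flow (+x) direction, so it
#' is negative upstream of the anchor; for the BV walls `s` increases from
#' the junction corner back toward the BV inlet. Reported positions of WSS
#' features are `|s|`, the unsigned distance to the dural entrance anchor.
#'
#' @param geometry a [build_geometry()] object.
#' @param label one of `"SSU"`, `"SSD"`, `"SSO_U"`, `"SSO_D"`, `"BVU"`, `"BVD"`.
#' @param step sampling step along the wall, mm; `NULL` gives endpoints only.
#' @return Data frame `x, y, s` with attributes `label`, `tangent`, `normal`
#'   (inward unit normal), and `open_end` (which end abuts an inlet/outlet
#'   face of the domain).
#' @export
wall_arclength <- function(geometry, label, step = NULL) {
  stopifnot(inherits(geometry, "junction_geometry"))
  if (!label %in% names(geometry$walls)) {
    stop("unknown wall label: ", label)
  }
  w <- geometry$walls[[label]]
  len <- w$s_to - w$s_from
  if (is.null(step)) {
    tloc <- c(0, len)
  } else {
    stopifnot(step > 0)
    tloc <- seq(0, len, by = step)
    if (tloc[length(tloc)] < len - 1e-9) tloc <- c(tloc, len)
  }
  dir <- (w$to - w$from) / len
  pts <- cbind(w$from[1] + tloc * dir[1], w$from[2] + tloc * dir[2])
  out <- data.frame(x = pts[, 1], y = pts[, 2], s = w$s_from + tloc)
  attr(out, "label") <- label
  attr(out, "tangent") <- w$tangent
  attr(out, "normal") <- w$normal
  attr(out, "open_end") <- w$open_end
  attr(out, "length") <- len
  out
}

#' Straight-channel geometry (validation case)
#'
#' A plain 2-D channel without a vein: two walls (`lower`, `upper`), a
#' velocity inlet on the left and the pressure outlet on the right. Used to
#' validate the solver against the plane-Poiseuille closed form
#' (wall shear `6 mu U / h` for mean velocity `U` and gap `h`).
#' Arc length `s` is anchored at mid-channel.
#'
#' @param width channel width, mm.
#' @param length channel length, mm.
#' @return A `"junction_geometry"`-compatible object with a degenerate
#'   (zero-width) vein, accepted by [rasterize()] and the WSS analysis.
#' @export
channel_geometry <- function(width = 8, length = 40) {
  stopifnot(width > 0, length > 0)
  L2 <- length / 2
  walls <- list(
    lower = list(from = c(-L2, 0), to = c(L2, 0), anchor = c(0, 0),
                 tangent = c(1, 0), normal = c(0, 1),
                 s_from = -L2, s_to = L2, open_end = "both"),
    upper = list(from = c(-L2, width), to = c(L2, width), anchor = c(0, width),
                 tangent = c(1, 0), normal = c(0, -1),
                 s_from = -L2, s_to = L2, open_end = "both")
  )
  structure(list(d_ss = width, d_bv = width, alpha = 90,
                 L_up = L2, L_down = L2, L_bv = 0,
                 entrance = c(0, width), axis = c(0, 1),
                 transverse = c(1, 0), mouth_span = 0,
                 corner_down = c(0, width), corner_up = c(0, width),
                 walls = walls),
            class = "junction_geometry")
}

# point-in-fluid test for the junction region (vectorised over x, y)
in_fluid <- function(geometry, x, y) {
  g <- geometry
  rect <- x >= -g$L_up & x <= g$L_down & y > 0 & y < g$d_ss
  rel_x <- x - g$entrance[1]; rel_y <- y - g$entrance[2]
  q <- rel_x * g$transverse[1] + rel_y * g$transverse[2]
  t <- rel_x * g$axis[1] + rel_y * g$axis[2]
  strip <- y >= g$d_ss & abs(q) < g$d_bv / 2 & t < g$L_bv
  rect | strip
}

# distance from points to a segment (vectorised over points)
dist_to_segment <- function(px, py, from, to) {
  vx <- to[1] - from[1]; vy <- to[2] - from[2]
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - from[1]) * vx + (py - from[2]) * vy) / L2, 0), 1)
  sqrt((px - (from[1] + t * vx))^2 + (py - (from[2] + t * vy))^2)
}

#' Rasterize a junction geometry to a solver grid
#'
#' Classifies a uniform Cartesian grid covering the junction into fluid,
#' solid, boundary-condition (inlet/outlet) and labelled wall cells. Cell
#' centers sit at `origin + (i - 1/2, j - 1/2) * spacing` (half-open cell
#' convention, grid cell (1,1) at the domain's lower-left corner). A cell is
#' fluid when its center lies inside the junction polygon; wall cells are
#' solid cells 4-adjacent to fluid, labelled by the nearest wall segment.
#' SSS inlet cells are the fluid cells of the first grid column, outlet
#' cells those of the last, and BV inlet cells the fluid layer within one
#' spacing of the oblique BV inlet face.
#'
#' For resolved wall shear the spacing must put at least 8 cells across the
#' narrowest channel (`spacing <= d_bv / 8`); walls parallel to the grid are
#' resolved most accurately when `d_ss` is an integer multiple of `spacing`.
#'
#' @param geometry a [build_geometry()] object.
#' @param spacing grid spacing, mm.
#' @return Object of class `"grid_mask"`: `cells` (integer matrix, 0 solid,
#'   1 fluid, 2 SSS inlet, 3 BV inlet, 4 outlet), `wall_label` (integer
#'   matrix, codes of [wall_arclength()] labels, 0 elsewhere), `bc_cells`
#'   (data frame of boundary-condition cells with inflow direction and
#'   normalised transverse coordinate), `spacing`, `origin`, and the source
#'   geometry.
#' @export
rasterize <- function(geometry, spacing) {
  g <- geometry
  stopifnot(inherits(g, "junction_geometry"), spacing > 0)
  if (spacing > g$d_bv / 8 + 1e-12) {
    stop("resolution error: spacing must be <= d_bv/8 = ",
         signif(g$d_bv / 8, 4), " mm (got ", spacing, ")")
  }
  h <- spacing
  # the domain box must cover the sinus and the full vein (an oblique vein
  # can overhang the sinus ends in x)
  wy <- unlist(lapply(g$walls, function(w) c(w$from[2], w$to[2])))
  y_top <- max(g$d_ss, wy) + h
  bv <- g$walls[intersect(c("BVU", "BVD"), names(g$walls))]
  bvx <- unlist(lapply(bv, function(w) c(w$from[1], w$to[1])))
  origin <- c(min(-g$L_up, if (length(bvx)) min(bvx) - h else Inf), 0)
  x_max <- max(g$L_down, if (length(bvx)) max(bvx) + h else -Inf)
  nx <- as.integer(ceiling((x_max - origin[1]) / h - 1e-9))
  ny <- as.integer(ceiling((y_top - origin[2]) / h - 1e-9))
  xc <- origin[1] + (seq_len(nx) - 0.5) * h
  yc <- origin[2] + (seq_len(ny) - 0.5) * h
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)
  fluid <- in_fluid(g, X, Y)
  cells <- matrix(0L, nx, ny)
  cells[fluid] <- 1L

  # BV inlet: fluid cells within one spacing of the inlet face (t = L_bv)
  rel_x <- X - g$entrance[1]; rel_y <- Y - g$entrance[2]
  t_ax <- rel_x * g$axis[1] + rel_y * g$axis[2]
  q_tr <- rel_x * g$transverse[1] + rel_y * g$transverse[2]
  if (g$L_bv > 0) {
    bv_inlet <- fluid & t_ax > g$L_bv - h & Y >= g$d_ss
    cells[bv_inlet] <- 3L
  }
  # SSS inlet / outlet: the first and last cell layers of the sinus channel
  cells[fluid & X < -g$L_up + h & Y < g$d_ss] <- 2L
  cells[fluid & X > g$L_down - h & Y < g$d_ss] <- 4L

  # wall cells: solid cells 4-adjacent to fluid, labelled by nearest segment
  solid <- cells == 0L
  nb_fluid <- matrix(FALSE, nx, ny)
  fl <- cells > 0L
  nb_fluid[-1, ] <- nb_fluid[-1, ] | fl[-nx, ]
  nb_fluid[-nx, ] <- nb_fluid[-nx, ] | fl[-1, ]
  nb_fluid[, -1] <- nb_fluid[, -1] | fl[, -ny]
  nb_fluid[, -ny] <- nb_fluid[, -ny] | fl[, -1]
  wall_cells <- which(solid & nb_fluid)
  wall_label <- matrix(0L, nx, ny)
  if (length(wall_cells) > 0) {
    px <- X[wall_cells]; py <- Y[wall_cells]
    d6 <- vapply(names(g$walls), function(lb) {
      w <- g$walls[[lb]]
      dist_to_segment(px, py, w$from, w$to)
    }, numeric(length(wall_cells)))
    d6 <- matrix(d6, nrow = length(wall_cells))
    wall_label[wall_cells] <- apply(d6, 1, which.min)
  }

  # boundary-condition cell table: index, code, inflow direction, transverse
  # coordinate normalised to [-1, 1] across the face (for parabolic profiles)
  idx2 <- which(cells == 2L); idx3 <- which(cells == 3L); idx4 <- which(cells == 4L)
  bc <- rbind(
    if (length(idx2)) data.frame(idx = idx2, code = 2L, dirx = 1, diry = 0,
                                 qn = (Y[idx2] - g$d_ss / 2) / (g$d_ss / 2)),
    if (length(idx3)) data.frame(idx = idx3, code = 3L,
                                 dirx = -g$axis[1], diry = -g$axis[2],
                                 qn = q_tr[idx3] / (g$d_bv / 2)),
    if (length(idx4)) data.frame(idx = idx4, code = 4L, dirx = 1, diry = 0,
                                 qn = (Y[idx4] - g$d_ss / 2) / (g$d_ss / 2))
  )
  structure(list(spacing = h, origin = origin, nx = nx, ny = ny,
                 cells = cells, wall_label = wall_label,
                 wall_legend = names(g$walls), bc_cells = bc,
                 geometry = g),
            class = "grid_mask")
}

#' @export
print.grid_mask <- function(x, ...) {
  cat(sprintf(paste0(
    "Junction grid mask: %d x %d cells at %.4g mm spacing\n",
    "  fluid %d, wall %d, SSS-inlet %d, BV-inlet %d, outlet %d\n"),
    x$nx, x$ny, x$spacing, sum(x$cells == 1L), sum(x$wall_label > 0L),
    sum(x$cells == 2L), sum(x$cells == 3L), sum(x$cells == 4L)))
  invisible(x)
}

#' Fluid area represented by a grid mask
#'
#' @param mask a [rasterize()] result.
#' @return Total area of fluid (including boundary-condition) cells, mm^2.
#' @export
fluid_area <- function(mask) {
  sum(mask$cells > 0L) * mask$spacing^2
}

#' Mirror a grid mask through the entrance-transverse line
#'
#' Reflects the mask through x = 0: the sinus inlet moves to the +x end and
#' blows in -x. On a right-angle junction (whose geometry is its own mirror
#' image) the solved flow field must be the reflection of the original one,
#' which makes this the basis of the solver's mirror-symmetry validation.
#'
#' @param mask a [rasterize()] grid mask.
#' @return The mirrored grid mask.
#' @export
mirror_mask <- function(mask) {
  m <- mask
  flip <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  m$cells <- flip(mask$cells)
  m$wall_label <- flip(mask$wall_label)
  bc <- mask$bc_cells
  ij <- arrayInd(bc$idx, c(mask$nx, mask$ny))
  ij[, 1] <- mask$nx + 1L - ij[, 1]
  bc$idx <- ij[, 1] + (ij[, 2] - 1L) * mask$nx
  bc$dirx <- -bc$dirx
  m$bc_cells <- bc
  m
}
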