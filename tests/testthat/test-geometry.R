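test_that("the vein mouth span follows the trigonometric closed form", {
  g <- build_geometry(d_bv = 2, alpha = 90)
  expect_equal(g$mouth_span, 2)
  g43 <- build_geometry(d_bv = 2, alpha = 43)
  expect_equal(g43$mouth_span, 2 / sin(43 * pi / 180), tolerance = 1e-12)
  expect_equal(g43$mouth_span, 2.932558, tolerance = 1e-6)
})

test_that("a right-angle junction is mirror-symmetric about the entrance", {
  g <- build_geometry(d_bv = 3, alpha = 90)
  expect_equal(g$corner_down[1], -g$corner_up[1])
  expect_equal(g$corner_down[2], g$corner_up[2])
  # BV walls are vertical and symmetric
  expect_equal(g$walls$BVU$to[1], -g$walls$BVD$to[1])
})

test_that("geometries at alpha and 180 - alpha are mirror images", {
  for (al in c(30, 43, 75)) {
    g1 <- build_geometry(d_bv = 2.5, alpha = al)
    g2 <- build_geometry(d_bv = 2.5, alpha = 180 - al)
    # reflection through x = 0 swaps the corners and the BV walls
    expect_equal(g1$corner_down[1], -g2$corner_up[1], tolerance = 1e-12)
    expect_equal(g1$walls$BVU$to[1], -g2$walls$BVD$to[1], tolerance = 1e-12)
    expect_equal(g1$walls$BVU$to[2], g2$walls$BVD$to[2], tolerance = 1e-12)
    expect_equal(g1$mouth_span, g2$mouth_span, tolerance = 1e-12)
  }
})

test_that("all cohort-extreme morphologies build at default lengths", {
  for (d in c(0.6, 1.2, 2.6, 5.8)) {
    for (al in c(10, 43, 90, 105, 170)) {
      expect_s3_class(build_geometry(d_bv = d, alpha = al),
                      "junction_geometry")
    }
  }
  expect_error(build_geometry(d_bv = 3, alpha = 0), "entry angle")
  expect_error(build_geometry(d_bv = 3, alpha = 185), "entry angle")
  # mouth wider than the upstream sinus segment
  expect_error(build_geometry(d_bv = 3, alpha = 2,
                              lengths = c(10, 60, 60)), "upstream")
  # vein too short for its oblique mouth
  expect_error(build_geometry(d_bv = 3, alpha = 10, lengths = c(30, 60, 6)),
               "too short")
})

test_that("wall arc lengths add up and anchor at the junction corners", {
  g <- build_geometry(d_bv = 3, alpha = 43, lengths = c(30, 60, 20))
  ssd <- wall_arclength(g, "SSD")
  ssu <- wall_arclength(g, "SSU")
  expect_equal(attr(ssd, "length"), 60 - g$mouth_span / 2, tolerance = 1e-12)
  # SSU + SSD + mouth span cover the full upper wall
  expect_equal(attr(ssu, "length") + attr(ssd, "length") + g$mouth_span,
               30 + 60, tolerance = 1e-12)
  # BVU is anchored (s = 0) at the corner it shares with SSU (upstream)
  bvu <- wall_arclength(g, "BVU")
  expect_equal(bvu$s[1], 0)
  expect_equal(c(bvu$x[1], bvu$y[1]), g$corner_up, tolerance = 1e-12)
  # s increases from the corner toward the BV inlet
  bvu5 <- wall_arclength(g, "BVU", step = 0.5)
  expect_true(all(diff(bvu5$s) > 0))
  expect_equal(max(bvu5$s), attr(bvu5, "length"))
  # sampled points advance by the requested step
  expect_equal(diff(bvu5$s)[1], 0.5)
  expect_error(wall_arclength(g, "XXX"), "unknown wall")
})

test_that("rasterized fluid area approaches the analytic channel area", {
  g <- channel_geometry(width = 8, length = 40)
  area_ref <- 8 * 40
  perim <- 2 * (8 + 40)
  errs <- vapply(c(0.6, 0.3, 0.15), function(h) {
    m <- rasterize(g, h)
    expect_lt(abs(fluid_area(m) - area_ref), 2 * h * perim)
    abs(fluid_area(m) - area_ref)
  }, 1)
  expect_true(all(diff(errs) <= 1e-9))   # refinement does not worsen the area
})

test_that("rasterization rejects too-coarse spacing", {
  g <- build_geometry(d_bv = 1.0, alpha = 90)
  expect_error(rasterize(g, 0.2), "resolution error")
  expect_s3_class(rasterize(g, 0.125), "grid_mask")
})

test_that("the junction mask is classified and labelled completely", {
  g <- build_geometry(d_bv = 3, alpha = 60, lengths = c(12, 25, 15))
  m <- rasterize(g, 0.25)
  expect_setequal(unique(as.vector(m$cells)), c(0L, 1L, 2L, 3L, 4L))
  # every solid cell 4-adjacent to fluid carries exactly one wall label
  fl <- m$cells > 0L
  nb <- matrix(FALSE, m$nx, m$ny)
  nb[-1, ] <- nb[-1, ] | fl[-m$nx, ]; nb[-m$nx, ] <- nb[-m$nx, ] | fl[-1, ]
  nb[, -1] <- nb[, -1] | fl[, -m$ny]; nb[, -m$ny] <- nb[, -m$ny] | fl[, -1]
  boundary <- which(!fl & nb)
  expect_true(all(m$wall_label[boundary] >= 1L))
  expect_true(all(m$wall_label[boundary] <= 6L))
  expect_equal(m$wall_legend, c("SSU", "SSD", "SSO_U", "SSO_D", "BVU", "BVD"))
  # inlet/outlet cells lie on the domain boundary columns or the BV end
  expect_true(all(which(m$cells == 2L, arr.ind = TRUE)[, 1] == 1L))
  expect_true(all(which(m$cells == 4L, arr.ind = TRUE)[, 1] == m$nx))
})

test_that("the right-angle mask is mirror-symmetric up to one cell", {
  g <- build_geometry(d_bv = 2, alpha = 90, lengths = c(20, 20, 10))
  m <- rasterize(g, 0.25)
  flipped <- m$cells[rev(seq_len(m$nx)), ]
  # compare fluid/solid classification (codes 2 and 4 swap under mirror)
  expect_equal(flipped > 0L, m$cells > 0L)
})
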