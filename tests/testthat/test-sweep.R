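# construct a results table like run_sweep() emits, without the solver
fake_results <- function(d, alpha, group = NULL,
                         min_SSD = NULL, pos_SSD = NULL,
                         min_BVU = NULL, pos_BVU = NULL) {
  n <- length(d)
  if (is.null(group)) group <- rep(c("anterior", "posterior"), length.out = n)
  df <- data.frame(id = sprintf("m%d", seq_len(n)), group = group,
                   d_bv = d, alpha = alpha, converged = TRUE,
                   stringsAsFactors = FALSE)
  df$min_SSD <- min_SSD %||% runif(n, 0.01, 0.5)
  df$pos_SSD <- pos_SSD %||% runif(n, 0, 20)
  df$min_BVU <- min_BVU %||% runif(n, 0.01, 0.5)
  df$pos_BVU <- pos_BVU %||% runif(n, 0, 10)
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the demarcation detector follows the maximal-ratio rule", {
  th <- demarcation_threshold(c(0.005, 0.008, 0.010, 0.3, 0.4))
  expect_true(th$found)
  expect_equal(th$pair, c(0.010, 0.3))
  expect_equal(th$wss_demarcation, sqrt(0.010 * 0.3), tolerance = 1e-12)
  expect_equal(th$wss_demarcation, 0.05477, tolerance = 1e-4)

  flat <- demarcation_threshold(c(1, 1, 1))
  expect_false(flat$found)
  expect_true(is.na(flat$wss_demarcation))

  expect_error(demarcation_threshold(c(0.1, 0.2)), "at least 3")
  expect_error(demarcation_threshold(c(-1, 0.2, 0.3)), "positive")
})

test_that("the demarcation is scale-equivariant to machine precision", {
  set.seed(21)
  for (rep in 1:20) {
    v <- exp(rnorm(30, -3, 1.5))
    c_ <- runif(1, 0.1, 100)
    t1 <- demarcation_threshold(v)
    t2 <- demarcation_threshold(c_ * v)
    expect_identical(t1$found, t2$found)
    if (t1$found) {
      expect_equal(t2$wss_demarcation, c_ * t1$wss_demarcation,
                   tolerance = 1e-12)
    }
  }
})

test_that("angle grouping bins, excludes thin veins, and counts correctly", {
  res <- fake_results(d = c(0.8, 1.2, 1.5, 2.0, 3.0, 4.0, 2.5),
                      alpha = c(40, 50, 30, 65, 80, 110, 170))
  gt <- classify_angle_groups(res)
  # d <= 1.2 excluded: veins 1 and 2 drop, leaving 30, 65, 80, 110, 170
  expect_equal(gt$n_excluded, 2L)
  tab <- gt$table
  n_by_bin <- tapply(tab$n, tab$group, unique)
  expect_equal(unname(n_by_bin[["[0,65)"]]), 1)     # 30
  expect_equal(unname(n_by_bin[["[65,105)"]]), 2)   # 65 (left-closed), 80
  expect_equal(unname(n_by_bin[["[105,180)"]]), 2)  # 110, 170
  # summaries match direct computation for one cell
  keep <- res$d_bv > 1.2 & res$alpha >= 65 & res$alpha < 105
  cell <- tab[tab$group == "[65,105)" & tab$wall == "SSD" &
                tab$metric == "min_value_pa", ]
  expect_equal(cell$mean, mean(res$min_SSD[keep]))
  expect_equal(cell$sd, sd(res$min_SSD[keep]))
})

test_that("bin populations are invariant to input ordering", {
  set.seed(31)
  res <- fake_results(d = runif(30, 1.3, 5), alpha = runif(30, 15, 165))
  g1 <- classify_angle_groups(res)
  g2 <- classify_angle_groups(res[sample(nrow(res)), ])
  expect_equal(g1$table[order(g1$table$group, g1$table$wall, g1$table$metric), ],
               g2$table[order(g2$table$group, g2$table$wall, g2$table$metric), ],
               ignore_attr = TRUE)
})

test_that("anterior/posterior comparison flags constructed separations", {
  # identical groups: F ~ 0, not significant
  base <- fake_results(d = rep(3, 10), alpha = rep(60, 10),
                       group = rep(c("anterior", "posterior"), each = 5),
                       min_BVU = rep(c(0.2, 0.21, 0.19, 0.2, 0.2), 2))
  gt0 <- compare_anterior_posterior(base)
  expect_gt(gt0$anova$min_BVU$p, 0.9)

  # posterior minima uniformly half the anterior minima: significant, ordered
  sep <- base
  sep$min_BVU[sep$group == "posterior"] <-
    sep$min_BVU[sep$group == "anterior"] / 2
  gt1 <- compare_anterior_posterior(sep)
  tabs <- gt1$table
  m_ant <- tabs$mean[tabs$group == "anterior" & tabs$wall == "BVU" &
                       tabs$metric == "min_value_pa"]
  m_pos <- tabs$mean[tabs$group == "posterior" & tabs$wall == "BVU" &
                       tabs$metric == "min_value_pa"]
  expect_lt(m_pos, m_ant)
  expect_lt(gt1$anova$min_BVU$p, 0.01)

  expect_error(compare_anterior_posterior(
    fake_results(d = c(2, 3), alpha = c(50, 60),
                 group = c("anterior", "anterior"))), "both")
})

test_that("percentage ratio rounds half-up as printed", {
  expect_equal(ratio_percent(0.005, 0.008), 63)   # 62.5 rounds up
  expect_equal(ratio_percent(0.005, 0.008, raw = TRUE), 62.5)
  expect_equal(ratio_percent(0.3, 0.3), 100)
  expect_equal(ratio_percent(0.2, 0.4), 50)
  expect_error(ratio_percent(1, 0), "denominator")
})

test_that("the predilection extent doubles the farthest minimum position", {
  expect_equal(predilection_extent(c(2.9, 0.3, 13.5)), 27)
  expect_equal(predilection_extent(c(0, 0, 0)), 0)
  expect_equal(predilection_extent(c(1, 2, 3)), 6)
  expect_error(predilection_extent(numeric(0)), "no positions")
})

test_that("stratified subsetting spans the morphology grid", {
  co <- suppressWarnings(generate_cohort(seed = 12))
  sub <- stratified_subset(co)
  expect_lte(nrow(sub), 12)
  expect_gt(nrow(sub), 3)
  expect_true(all(sub$id %in% co$id))
  # at most one representative per occupied diameter x angle cell
  db <- cut(sub$diameter_mm, c(0, 1.2, 2.5, 4, Inf))
  ab <- cut(sub$entry_angle_deg, c(0, 65, 105, 180))
  expect_false(any(duplicated(paste(db, ab))))
})

test_that("run_sweep records every model as a result or a failure", {
  cfg <- junction_test_config()
  cfg$spacing <- 0.4    # coarse: only valid for d >= 3.2
  co <- validate_cohort(data.frame(
    id = c("ok1", "bad1"),
    group = c("anterior", "posterior"),
    diameter_mm = c(4.0, 1.0),     # 1.0 mm violates spacing <= d/8
    entry_angle_deg = c(90, 45), stringsAsFactors = FALSE))
  sw <- suppressWarnings(run_sweep(co, cfg))
  expect_s3_class(sw, "bv_sweep")
  expect_equal(nrow(sw$results) + nrow(sw$failures), 2L)
  expect_equal(sw$failures$id, "bad1")
  expect_match(sw$failures$message, "resolution")
  expect_true(all(c("min_SSD", "pos_BVU", "stable_SSO_D") %in%
                    names(sw$results)))
})
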