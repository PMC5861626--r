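# quadrature oracle: truncated-normal mean/SD by numerical integration
truncnorm_moments_quad <- function(mu, sigma, lo, hi) {
  Z <- integrate(function(x) dnorm(x, mu, sigma), lo, hi,
                 rel.tol = 1e-12)$value
  m1 <- integrate(function(x) x * dnorm(x, mu, sigma), lo, hi,
                  rel.tol = 1e-12)$value / Z
  m2 <- integrate(function(x) x^2 * dnorm(x, mu, sigma), lo, hi,
                  rel.tol = 1e-12)$value / Z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

test_that("closed-form truncated moments agree with quadrature", {
  cases <- list(c(3, 1.1, 0.8, 5.8), c(2, 0.9, 0.6, 5.2),
                c(50, 30, 10, 90), c(-1, 2, 0, 3))
  for (cs in cases) {
    expect_equal(unname(truncnorm_moments(cs[1], cs[2], cs[3], cs[4])),
                 unname(truncnorm_moments_quad(cs[1], cs[2], cs[3], cs[4])),
                 tolerance = 1e-8)
  }
})

test_that("moment matching solves the latent truncated-normal parameters", {
  # no truncation: identity
  p <- solve_truncnorm_params(3, 1.1)
  expect_equal(p$mu, 3)
  expect_equal(p$sigma, 1.1)

  # symmetric bounds about the mean: mu equals the target mean
  p <- solve_truncnorm_params(2, 0.5, 1, 3)
  expect_equal(p$mu, 2, tolerance = 1e-6)
  expect_true(p$feasible)

  # published posterior diameter cell, checked against quadrature
  p <- solve_truncnorm_params(3.0, 1.1, 0.8, 5.8)
  expect_true(p$feasible)
  mo <- truncnorm_moments_quad(p$mu, p$sigma, 0.8, 5.8)
  expect_equal(unname(mo["mean"]), 3.0, tolerance = 1e-6)
  expect_equal(unname(mo["sd"]), 1.1, tolerance = 1e-6)
})

test_that("infeasible moments are detected and the nearest fit pins the mean", {
  # SD 25 on [10, 90] exceeds the log-concave bound (80 / sqrt(12) = 23.09)
  expect_error(solve_truncnorm_params(43, 25, 10, 90), "no truncated normal")
  p <- solve_truncnorm_params(43, 25, 10, 90, on_infeasible = "nearest")
  expect_false(p$feasible)
  expect_equal(unname(p$achieved["mean"]), 43, tolerance = 1e-4)
  expect_gt(unname(p$achieved["sd"]), 21)   # close to the family supremum
  expect_lt(unname(p$achieved["sd"]), 80 / sqrt(12))
})

test_that("generated cohorts have exact sizes, ids and hard support", {
  co <- suppressWarnings(generate_cohort(seed = 1))
  expect_equal(nrow(co), 137L)
  ant <- co[co$group == "anterior", ]
  pos <- co[co$group == "posterior", ]
  expect_equal(nrow(ant), 62L)
  expect_equal(nrow(pos), 75L)
  expect_equal(pos$id, sprintf("posterior_%d", 1:75))
  # support is exact, never clipped values outside the published ranges
  expect_true(all(ant$diameter_mm >= 0.6 & ant$diameter_mm <= 5.2))
  expect_true(all(ant$entry_angle_deg >= 40 & ant$entry_angle_deg <= 170))
  expect_true(all(pos$diameter_mm >= 0.8 & pos$diameter_mm <= 5.8))
  expect_true(all(pos$entry_angle_deg >= 10 & pos$entry_angle_deg <= 90))
})

test_that("a zero-size group yields zero records", {
  sp <- default_group_specs()
  sp$anterior$n <- 0L
  co <- suppressWarnings(generate_cohort(sp, seed = 1))
  expect_equal(sum(co$group == "anterior"), 0L)
  expect_equal(sum(co$group == "posterior"), 75L)
})

test_that("identical config and seed give a byte-identical cohort CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(suppressWarnings(generate_cohort(seed = 99)), f1)
  write_cohort(suppressWarnings(generate_cohort(seed = 99)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed gives a different cohort
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(suppressWarnings(generate_cohort(seed = 100)), f3)
  expect_false(identical(readBin(f1, "raw", file.size(f1)),
                         readBin(f3, "raw", file.size(f3))))
})

test_that("sample moments recover the published targets within 3 SE", {
  co <- suppressWarnings(generate_cohort(seed = 2026))
  specs <- default_group_specs()
  for (g in c("anterior", "posterior")) {
    sp <- specs[[g]]
    sub <- co[co$group == g, ]
    se_mean_d <- sp$diameter_sd / sqrt(sp$n)
    expect_lt(abs(mean(sub$diameter_mm) - sp$diameter_mean), 3 * se_mean_d)
    expect_lt(abs(sd(sub$diameter_mm) - sp$diameter_sd),
              3 * sp$diameter_sd / sqrt(2 * sp$n))
    se_mean_a <- sp$angle_mean / sqrt(sp$n)
    expect_lt(abs(mean(sub$entry_angle_deg) - sp$angle_mean),
              3 * sp$angle_sd / sqrt(sp$n))
  }
})

test_that("the generator is unbiased across replicate cohorts", {
  # 200 replicates of the posterior group; the grand mean of the sample
  # means must sit within 2 Monte-Carlo SEs of the 3.0 mm target
  sp <- list(posterior = default_group_specs()$posterior)
  means <- vapply(1:200, function(s) {
    co <- suppressWarnings(generate_cohort(sp, seed = 1000 + s))
    mean(co$diameter_mm)
  }, 1)
  mc_se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 3.0), 2 * mc_se + 1e-9)
})

test_that("the correlation knob induces the requested dependence", {
  sp <- list(posterior = default_group_specs()$posterior)
  sp$posterior$n <- 400L
  co_neg <- suppressWarnings(generate_cohort(sp, seed = 5, correlation = -0.7))
  co_ind <- suppressWarnings(generate_cohort(sp, seed = 5, correlation = 0))
  expect_lt(cor(co_neg$diameter_mm, co_neg$entry_angle_deg), -0.5)
  expect_lt(abs(cor(co_ind$diameter_mm, co_ind$entry_angle_deg)), 0.15)
})
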