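test_that("identical vectors give zero bias and degenerate LOA", {
  x <- c(50.2, 61.7, 48.3, 70.1, 55.5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$bias_sd, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
})

test_that("hand-worked example d = {1,2,3} reproduces all derived cells", {
  ref <- c(10, 10, 10)
  ba <- bland_altman(ref, ref + c(1, 2, 3))
  expect_equal(ba$bias, 2)
  expect_equal(ba$bias_sd, 1)
  expect_equal(ba$bias_sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0.04, 3.96))
  # t(0.975, 2) = 4.3027
  expect_equal(ba$bias_ci, c(-0.4841377, 4.4841377), tolerance = 1e-6)
})

test_that("raw-data and summary-statistics routes agree exactly", {
  set.seed(42)
  ref <- rnorm(50, 55, 8)
  tst <- ref + rnorm(50, 6, 7)
  d <- tst - ref
  a <- bland_altman(ref, tst)
  b <- bland_altman_from_summary(mean(d), sd(d), 50)
  for (f in c("bias", "bias_sd", "bias_sem", "bias_ci", "loa_lower",
              "loa_upper", "loa_sem", "loa_lower_ci", "loa_upper_ci"))
    expect_identical(a[[f]], b[[f]])
})

test_that("swapping test and reference negates bias and mirrors the LOA", {
  set.seed(7)
  ref <- rnorm(30, 50, 5); tst <- ref + rnorm(30, 3, 4)
  a <- bland_altman(ref, tst)
  b <- bland_altman(tst, ref)
  expect_equal(b$bias, -a$bias)
  expect_equal(b$loa_lower, -a$loa_upper)
  expect_equal(b$loa_upper, -a$loa_lower)
  expect_equal(b$loa_sem, a$loa_sem)
})

test_that("structural invariants hold across random summary inputs", {
  set.seed(1)
  for (i in 1:50) {
    ba <- bland_altman_from_summary(runif(1, -10, 10), runif(1, 0.1, 12),
                                    sample(3:300, 1))
    expect_lt(ba$loa_lower, ba$bias)
    expect_gt(ba$loa_upper, ba$bias)
    expect_true(ba$bias_ci[1] < ba$bias && ba$bias < ba$bias_ci[2])
    expect_equal(ba$loa_upper - ba$loa_lower, 2 * ba$z * ba$bias_sd)
  }
})

test_that("a known injected offset is recovered within its confidence interval", {
  set.seed(99)
  delta <- 6
  ref <- rnorm(96, 55, 9)
  tst <- ref + delta + rnorm(96, 0, 7.5)
  ba <- bland_altman(ref, tst)
  expect_lt(abs(ba$bias - delta), 3 * ba$bias_sem)
  expect_true(ba$bias_ci[1] < delta && delta < ba$bias_ci[2])
})

test_that("bland_altman rejects malformed input", {
  expect_error(bland_altman(1:5, 1:4), "length")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
  expect_error(bland_altman_from_summary(1, -2, 10), "sd")
})

test_that("ratio summary partitions at 1 with ties counted separately", {
  r <- ratio_summary(c(0.9, 0.95, 1.1, 1.2) * 50, rep(50, 4))
  expect_equal(r$pct_under, 50)
  expect_equal(r$pct_over, 50)
  expect_equal(r$under$mean, 0.925)
  expect_equal(r$over$mean, 1.15)
  expect_equal(r$over$median, 1.15)
  expect_equal(r$n_tie, 0)

  tie <- ratio_summary(rep(3, 5), rep(3, 5))
  expect_equal(tie$n_tie, 5)
  expect_equal(tie$n_under + tie$n_over, 0)
  expect_true(is.na(tie$under$mean))

  over <- ratio_summary(1.1 * c(40, 50, 60), c(40, 50, 60))
  expect_equal(over$pct_over, 100)
  expect_equal(over$over$mean, 1.1)
  expect_error(ratio_summary(1:3, c(1, 0, 2)), "positive")
})

test_that("ratio partitions always bracket their medians", {
  set.seed(3)
  for (i in 1:20) {
    ref <- runif(40, 30, 80)
    tst <- ref * runif(40, 0.7, 1.7)
    r <- ratio_summary(tst, ref)
    expect_equal(r$n_under + r$n_over + r$n_tie, 40)
    if (r$n_under > 0)
      expect_true(r$under$min <= r$under$median && r$under$median <= r$under$max)
    if (r$n_over > 0)
      expect_true(r$over$min <= r$over$median && r$over$median <= r$over$max)
  }
})

test_that("r-squared and OLS fit behave on exact and independent data", {
  x <- seq(1, 20)
  expect_equal(correlation_r2(x, 2 * x + 1), 1)
  f <- suppressWarnings(linear_fit(x, 2 * x + 1))  # exact fit warns in summary.lm
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  set.seed(8)
  expect_lt(correlation_r2(rnorm(1e4), rnorm(1e4)), 0.01)
  expect_error(correlation_r2(rep(1, 5), 1:5), "constant")
})

test_that("r-squared is invariant under positive affine maps", {
  set.seed(12)
  x <- rnorm(100); y <- 0.6 * x + rnorm(100)
  base <- correlation_r2(x, y)
  expect_equal(correlation_r2(3 * x + 7, y), base)
  expect_equal(correlation_r2(x, 0.1 * y - 2), base)
})

test_that("confidence band contains the fit and narrows at the mean of x", {
  set.seed(21)
  x <- runif(60, 0, 10); y <- 3 + 1.5 * x + rnorm(60)
  f <- linear_fit(x, y, band_at = c(mean(x), 0, 10))
  expect_true(all(f$band$lwr < f$band$fit & f$band$fit < f$band$upr))
  w <- f$band$upr - f$band$lwr
  expect_true(w[1] < w[2] && w[1] < w[3])
})

test_that("cohort table summarises per sex with Welch p-values", {
  set.seed(5)
  d <- data.frame(sex = rep(c("male", "female"), each = 30),
                  weight_kg = c(rnorm(30, 82, 10), rnorm(30, 67, 10)))
  tb <- cohort_table(d, "weight_kg")
  expect_equal(nrow(tb), 2)
  m <- tb[tb$sex == "male", ]
  expect_true(m$min <= m$mean && m$mean <= m$max)
  expect_lt(tb$p_value[1], 0.01)
  # identical samples -> p ~ 1
  d2 <- data.frame(sex = rep(c("male", "female"), each = 10),
                   v = rep(rnorm(10), 2))
  expect_gt(cohort_table(d2, "v")$p_value[1], 0.999)
  # single subject: SD absent
  d3 <- data.frame(sex = "male", v = 5)
  expect_true(is.na(cohort_table(d3, "v", p_values = FALSE)$sd))
  expect_error(cohort_table(data.frame(sex = character(), v = numeric()),
                            "v"), "empty")
})
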