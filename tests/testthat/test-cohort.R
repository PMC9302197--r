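test_that("cohort generation is deterministic for a fixed seed", {
  p <- cohort_params(n_men = 20, n_women = 20, seed = 123)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  p2 <- cohort_params(n_men = 20, n_women = 20, seed = 124)
  expect_false(identical(simulate_cohort(p)$weight_kg,
                         simulate_cohort(p2)$weight_kg))
})

test_that("records satisfy the demographic invariants", {
  coh <- simulate_cohort(cohort_params(n_men = 150, n_women = 150, seed = 2))
  expect_true(all(coh$height_cm >= 120 & coh$height_cm <= 220))
  expect_true(all(coh$weight_kg >= 30 & coh$weight_kg <= 140))
  expect_true(all(coh$injected_mbq > 0))
  expect_true(all(coh$uptake_min >= 50 & coh$uptake_min <= 70))
  expect_true(all(coh$sex %in% c("male", "female")))
  expect_equal(sum(coh$sex == "male"), 150)
  # injected activity is exactly 5.2 MBq/kg
  expect_equal(coh$injected_mbq, 5.2 * coh$weight_kg)
})

test_that("sample weight mean converges to the calibrated cohort value", {
  coh <- simulate_cohort(cohort_params(n_men = 96, n_women = 0, seed = 31))
  expect_lt(abs(mean(coh$weight_kg) - 82.2), 3 * 17.5 / sqrt(96))
})

test_that("configured moments are recovered within 2% at n = 1e4", {
  coh <- simulate_cohort(cohort_params(n_men = 10000, n_women = 10000,
                                       seed = 11))
  for (s in c("male", "female")) {
    d <- coh[coh$sex == s, ]
    sp <- sex_params(s)
    chk <- function(x, par, what) {
      expect_lt(abs(mean(x) - par["mean"]) / par["mean"], 0.02,
                label = paste(s, what, "mean"))
      expect_lt(abs(sd(x) - par["sd"]) / par["sd"], 0.02,
                label = paste(s, what, "sd"))
    }
    chk(d$height_cm, sp$height, "height")
    chk(d$bmi, sp$bmi, "bmi")
    chk(d$true_fat_cm2, sp$fat, "fat")
    chk(d$true_sma_cm2, sp$sma, "sma")
  }
})

test_that("SMA-weight correlation matches the configured level", {
  coh <- simulate_cohort(cohort_params(n_men = 10000, n_women = 10000,
                                       seed = 11))
  m <- coh[coh$sex == "male", ]
  expect_true(cor(m$weight_kg, m$true_sma_cm2)^2 > 0.29 &&
              cor(m$weight_kg, m$true_sma_cm2)^2 < 0.35)
  # independence case: configured r2 = 0 gives |r| < 0.3 at n = 200
  p0 <- cohort_params(n_men = 200, n_women = 0, seed = 5,
                      men = modifyList(sex_params("male"),
                                       list(r2_sma_weight = 0)))
  d0 <- simulate_cohort(p0)
  expect_lt(abs(cor(d0$weight_kg, d0$true_sma_cm2)), 0.3)
})

test_that("conditional SMA calibration matches the closed form", {
  cal <- sma_calibration(162.3, 29.2, 82.2, 17.5, 0.32)
  expect_equal(cal$slope, sqrt(0.32) * 29.2 / 17.5)
  expect_equal(cal$slope, 0.944, tolerance = 1e-3)
  expect_equal(cal$intercept, 84.7, tolerance = 1e-3)
  expect_equal(cal$resid_sd, 24.1, tolerance = 1e-2)
  # simulation check of the decomposition: regressing simulated SMA on
  # weight recovers the calibrated slope
  coh <- simulate_cohort(cohort_params(n_men = 10000, n_women = 0, seed = 13))
  fit <- lm(true_sma_cm2 ~ weight_kg, data = coh)
  expect_equal(unname(coef(fit)[2]), cal$slope, tolerance = 0.06)
  expect_equal(sd(resid(fit)), cal$resid_sd, tolerance = 0.5)
})

test_that("moment-matched truncated normal delivers the requested moments", {
  set.seed(17)
  x <- rtnorm_moments(20000, mean = 27, sd = 5.4, lower = 17.6, upper = 44.5)
  expect_true(all(x >= 17.6 & x <= 44.5))
  expect_lt(abs(mean(x) - 27) / 27, 0.02)
  expect_lt(abs(sd(x) - 5.4) / 5.4, 0.02)
  # infeasible SD on a narrow interval is rejected up front
  expect_error(rtnorm_moments(10, 0, 10, -1, 1), "not attainable")
  expect_error(rtnorm_moments(10, 5, 1, 6, 10), "bracket")
})

test_that("parameter validation rejects impossible cohorts", {
  expect_error(cohort_params(n_men = 0, n_women = 0), "at least one")
  expect_error(cohort_params(uptake_min_range = c(70, 50)), "uptake")
  expect_error(cohort_params(activity_mbq_per_kg = 0), "positive")
})
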