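test_that("expected distance follows the piecewise law and its oracle", {
  m <- saturation_model()
  # pre-onset linear zone, then halved slopes per 10-MY window:
  # 20 + 5, 20 + 5 + 2.5 + 1.25 + 0.625
  expect_equal(expected_distance(m, 10), 10)
  expect_equal(expected_distance(m, 30), 25)
  expect_equal(expected_distance(m, 60), 29.375)
  # stepwise-integration oracle on a fine grid
  grid <- seq(0, 100, by = 0.1)
  expect_lt(max(abs(expected_distance(m, grid) - integrate_saturation(m, grid))),
            1e-9)
  # continuity and strict monotonicity
  expect_true(all(diff(expected_distance(m, grid)) > 0))
  # no saturation when decay = 1
  m1 <- saturation_model(decay = 1)
  expect_equal(expected_distance(m1, grid), grid)
  expect_error(expected_distance(m, -1), "non-negative")
  expect_error(saturation_model(rate = 0))
  expect_error(saturation_model(decay = 1.5))
})

test_that("inversion is the exact inverse of the distance map", {
  m <- saturation_model()
  expect_equal(invert_distance(m, 0), 0)
  expect_equal(invert_distance(m, 10), 10)
  # oracle: bisection on expected_distance
  bisect <- function(d) {
    lo <- 0; hi <- 1e4
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (expected_distance(m, mid) < d) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(invert_distance(m, 25), bisect(25), tolerance = 1e-8)
  expect_equal(invert_distance(m, 25), 30)
  ts <- c(seq(0, 100, by = 0.37), 19.999, 20, 20.001, 30, 50, 200)
  expect_lt(max(abs(invert_distance(m, expected_distance(m, ts)) - ts)), 1e-9)
  # also under a non-default parameterisation
  m2 <- saturation_model(rate = 2.5, onset = 7, decay = 0.8, window = 3.5)
  expect_lt(max(abs(invert_distance(m2, expected_distance(m2, ts)) - ts)), 1e-9)
  expect_error(invert_distance(m, -0.1), "non-negative")
})

test_that("apparent rate and single-calibration estimates match the model", {
  m <- saturation_model()
  expect_equal(apparent_rate(m, 10), 1)
  expect_equal(apparent_rate(m, 30), 25 / 30)
  expect_equal(apparent_rate(m, 60), 29.375 / 60)
  expect_error(apparent_rate(m, 0), "positive")
  # calibration in the unsaturated zone dates unsaturated nodes exactly
  expect_equal(estimated_age(m, 15, cal_age = 10), 15)
  # deep calibration inflates young nodes; shallow calibration truncates deep
  expect_equal(estimated_age(m, 10, cal_age = 30), 12)
  expect_equal(estimated_age(m, 40, cal_age = 10), 27.5)
})

test_that("zero-bias zone is exact and bias signs follow calibration depth", {
  m <- saturation_model()
  young <- seq(0, 20, by = 0.25)
  expect_equal(estimated_age(m, young, cal_age = 10), young)
  expect_equal(estimated_age(m, young, cal_age = 20), young)
  # deep calibrations overestimate young nodes, worse with calibration age
  deep_cals <- seq(25, 70, by = 5)
  est10 <- vapply(deep_cals, function(a) estimated_age(m, 10, a), numeric(1))
  expect_true(all(est10 > 10))
  expect_true(all(diff(est10) > 0))
  # any calibration underestimates sufficiently old nodes
  expect_lt(estimated_age(m, 80, cal_age = 10), 80)
  expect_lt(estimated_age(m, 80, cal_age = 30), 80)
  expect_lt(estimated_age(m, 80, cal_age = 60), 80)
})

test_that("pooled rates combine calibrations by age-weighted least squares", {
  m <- saturation_model()
  # explicit through-origin least-squares oracle
  ls_fit <- function(ages) {
    d <- expected_distance(m, ages)
    unname(stats::lm(d ~ 0 + ages)$coefficients)
  }
  expect_equal(pooled_rate(m, c(10, 60)), ls_fit(c(10, 60)))
  expect_equal(pooled_rate(m, c(10, 60)), (10 * 10 + 60 * 29.375) / 3700)
  # pooled rate lies between the apparent rates, closer to the old one
  r_young <- apparent_rate(m, 10); r_old <- apparent_rate(m, 60)
  r_pool <- pooled_rate(m, c(10, 60))
  expect_true(r_pool > r_old && r_pool < r_young)
  expect_lt(abs(r_pool - r_old), abs(r_pool - r_young))
  # equal-weight pooling is selectable and differs
  r_mean <- pooled_rate(m, c(10, 60), pooling = "mean")
  expect_equal(r_mean, mean(c(r_young, r_old)))
  expect_gt(r_mean, r_pool)
  expect_error(pooled_rate(m, numeric()), "empty")
})

test_that("bias profiles classify deviations by sign and tolerance", {
  m <- saturation_model()
  prof <- bias_profile(m, c(5, 15, 20), cal_age = 10)
  expect_s3_class(prof, "tbl_df")
  expect_true(all(prof$class == "0"))
  expect_equal(prof$estimated_age, prof$true_age)

  two <- bias_profile(m, 10, cal_age = c(10, 60))
  expect_equal(two$estimated_age, 10 / 0.5033784, tolerance = 1e-4)
  expect_equal(as.character(two$class), "+")

  one_deep <- bias_profile(m, 10, cal_age = 60)
  expect_equal(one_deep$estimated_age, 10 / (29.375 / 60), tolerance = 1e-6)
  expect_equal(one_deep$estimated_age, 20.42553, tolerance = 1e-4)
  expect_equal(as.character(one_deep$class), "+")

  expect_error(bias_profile(m, numeric(), 10), "empty")
  expect_error(bias_profile(m, 10, numeric()), "empty")
  # tolerance moves the class boundary
  p <- bias_profile(m, 25, cal_age = 30, tolerance = 0.2)
  expect_equal(as.character(p$class), "0")
  p <- bias_profile(m, 25, cal_age = 30, tolerance = 0.01)
  expect_equal(as.character(p$class), "+")
})

test_that("percent/proportion helpers are mutual inverses", {
  x <- c(0, 12.5, 100)
  expect_equal(prop_to_pct(pct_to_prop(x)), x)
})
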