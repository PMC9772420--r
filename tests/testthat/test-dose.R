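test_that("Garwood limits match the chi-squared closed form and poisson.test", {
  ci0 <- poisson_exact_ci(0)
  expect_equal(ci0$lower_mean, 0)
  expect_equal(ci0$upper_mean, 3.688879, tolerance = 1e-6)

  ci10 <- poisson_exact_ci(10)
  expect_equal(ci10$lower_mean, 4.795389, tolerance = 1e-6)
  expect_equal(ci10$upper_mean, 18.39036, tolerance = 1e-6)

  # independent oracle: R's exact Poisson test
  for (x in c(0, 1, 3, 10, 42, 137)) {
    ref <- stats::poisson.test(x)$conf.int
    ci <- poisson_exact_ci(x)
    expect_equal(ci$lower_mean, ref[1], tolerance = 1e-9)
    expect_equal(ci$upper_mean, ref[2], tolerance = 1e-9)
  }

  expect_error(poisson_exact_ci(-1), class = "dcadose_input_error")
  expect_error(poisson_exact_ci(2.5), class = "dcadose_input_error")
  expect_error(poisson_exact_ci(3, level = 1), class = "dcadose_input_error")
})

test_that("exact intervals are conservative for a known Poisson mean", {
  set.seed(77)
  x <- rpois(10000, 3)
  ci <- poisson_exact_ci(x)
  coverage <- mean(ci$lower_mean <= 3 & 3 <= ci$upper_mean)
  expect_gte(coverage, 0.95)
})

test_that("curve inversion follows the closed form", {
  curve <- make_curve(C = 0.06, alpha = 0.07, beta = 0.02)
  expect_equal(merkle_point_estimate(curve, 0.28), 2, tolerance = 1e-12)
  expect_equal(merkle_point_estimate(curve, 0.06), 0)
  expect_equal(merkle_point_estimate(curve, 0.01), 0)

  lin <- make_curve(C = 0.06, alpha = 0.07, beta = 0)
  expect_equal(merkle_point_estimate(lin, 0.2), 2, tolerance = 1e-12)

  # round trip on a dense grid
  d <- seq(0, 4, by = 0.01)
  y <- 0.06 + 0.07 * d + 0.02 * d^2
  expect_equal(merkle_point_estimate(curve, y), d, tolerance = 1e-9)
})

test_that("triage bins follow the right-closed convention", {
  expect_identical(triage_category(c(0.4, 1, 1.5, 2, 3, 4, 5, 6, 7)),
                   c("<1", "<1", "1-2", "1-2", "2-4", "2-4", "4-6", "4-6",
                     ">6"))
  expect_error(triage_category(-0.1), class = "dcadose_input_error")
})

test_that("with a collapsed envelope the dose limits equal the closed form", {
  curve <- make_curve(vcov = matrix(0, 3, 3))
  est <- estimate_dose(curve, n_cells = 500, n_dicentrics = 140)
  expect_equal(est$dose_gy, merkle_point_estimate(curve, 140 / 500),
               tolerance = 1e-9)
  expect_equal(est$dose_lower_gy,
               merkle_point_estimate(curve, est$yield_lower),
               tolerance = 1e-5)
  expect_equal(est$dose_upper_gy,
               merkle_point_estimate(curve, est$yield_upper),
               tolerance = 1e-5)
})

test_that("low-count low-dose observations give an NA lower dose limit", {
  curve <- make_curve(vcov = diag(c(1e-5, 5e-5, 4e-6)))
  est <- estimate_dose(curve, n_cells = 500, n_dicentrics = 40)
  # lower yield limit sits below the upper envelope at D = 0, so the curves
  # never intersect
  expect_lt(est$yield_lower, curve_envelope(curve, 0)$upper)
  expect_true(is.na(est$dose_lower_gy))
  expect_false(is.na(est$dose_upper_gy))
  expect_identical(est$triage_category, "<1")

  # a high-count observation keeps both limits
  est2 <- estimate_dose(curve, n_cells = 500, n_dicentrics = 230)
  expect_false(is.na(est2$dose_lower_gy))
  expect_lte(est2$dose_lower_gy, est2$dose_gy)
  expect_lte(est2$dose_gy, est2$dose_upper_gy)
})

test_that("dose limits are monotone in the observed count", {
  curve <- make_curve(vcov = diag(c(1e-5, 5e-5, 4e-6)))
  uppers <- vapply(c(20, 60, 120, 200, 300), function(x) {
    estimate_dose(curve, n_cells = 500, n_dicentrics = x)$dose_upper_gy
  }, numeric(1))
  expect_true(all(diff(uppers) > 0))
  points <- merkle_point_estimate(curve, c(0.1, 0.2, 0.4, 0.6))
  expect_true(all(diff(points) > 0))
})

test_that("bisection limits agree with a fine-grid envelope scan", {
  set.seed(4242)
  n_na <- 0
  for (i in 1:100) {
    curve <- random_curve()
    n_cells <- sample(150:2000, 1)
    x <- sample(0:150, 1)
    obs <- yield_observation(n_cells, x)
    oracle <- grid_oracle_limits(curve, obs$yield_lower, obs$yield_upper)
    est <- estimate_dose(curve, n_cells, x)
    grid_step <- 20 / 1e4
    expect_identical(is.na(est$dose_lower_gy), is.na(oracle$lower))
    if (!is.na(oracle$lower)) {
      expect_lt(abs(est$dose_lower_gy - oracle$lower), grid_step + 1e-5)
    } else {
      n_na <- n_na + 1
    }
    if (!is.na(oracle$upper)) {
      expect_lt(abs(est$dose_upper_gy - oracle$upper), grid_step + 1e-5)
    }
  }
  # the sampled cases exercise both the NA and the defined branch
  expect_gt(n_na, 0)
  expect_lt(n_na, 100)
})

test_that("estimates order and label correctly across observed yields", {
  curve <- make_curve(vcov = diag(c(2e-5, 1e-4, 1e-5)))
  for (x in c(35, 80, 160, 260)) {
    est <- estimate_dose(curve, n_cells = 500, n_dicentrics = x)
    if (!is.na(est$dose_lower_gy)) {
      expect_lte(est$dose_lower_gy, est$dose_gy)
    }
    expect_lte(est$dose_gy, est$dose_upper_gy)
    expect_identical(est$triage_category, triage_category(est$dose_gy))
  }
})
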