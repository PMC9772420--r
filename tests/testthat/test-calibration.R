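test_that("yield aggregation is per-dose arithmetic and additive", {
  tbl <- make_records(rep(46, 100), dic = c(rep(1, 7), rep(0, 93)), dose = 1)
  pts <- aggregate_yields(tbl)
  expect_equal(pts$n_cells, 100)
  expect_equal(pts$n_dicentrics, 7)
  expect_equal(pts$yield, 0.07)

  zero <- aggregate_yields(make_records(rep(46, 10), dic = 0, dose = 0))
  expect_equal(zero$yield, 0)

  both <- aggregate_yields(dplyr::bind_rows(
    tbl, make_records(rep(46, 50), dic = c(rep(1, 5), rep(0, 45)), dose = 1,
                      donor = "S2")))
  expect_equal(both$n_cells, 150)
  expect_equal(both$n_dicentrics, 12)
})

test_that("noiseless linear-quadratic data are recovered exactly", {
  doses <- c(0, 0.5, 1, 2, 3, 4)
  pts <- tibble::tibble(
    dose_gy = doses, n_cells = 1000,
    n_dicentrics = 1000 * (0.06 + 0.07 * doses + 0.02 * doses^2)
  )
  curve <- fit_dose_response(pts)
  expect_equal(unname(curve$coefficients), c(0.06, 0.07, 0.02),
               tolerance = 1e-6)
  # exact data are equidispersed, so the scale floor engages
  expect_equal(curve$dispersion_scale, 1)
})

test_that("fewer than four distinct doses is insufficient", {
  pts <- tibble::tibble(dose_gy = c(0, 1, 2), n_cells = 500,
                        n_dicentrics = c(30, 80, 150))
  expect_error(fit_dose_response(pts), class = "dcadose_insufficient_data")
})

test_that("simulated Poisson counts recover the pooled coefficients", {
  doses <- c(0, 0.5, 1, 2, 3, 4)
  truth <- c(0.06, 0.07, 0.02)
  set.seed(1203)
  x <- vapply(doses,
              function(d) sum(rpois(5000, truth[1] + truth[2] * d +
                                      truth[3] * d^2)),
              numeric(1))
  curve <- fit_dose_response(tibble::tibble(dose_gy = doses, n_cells = 5000,
                                            n_dicentrics = x))
  expect_true(all(abs(curve$coefficients - truth) <= 3 * curve$se))
})

test_that("quasi-Poisson scale never shrinks below the Poisson fit", {
  set.seed(5)
  doses <- c(0, 0.5, 1, 2, 3, 4)
  for (i in 1:10) {
    x <- vapply(doses, function(d) sum(rpois(800, 0.05 + 0.08 * d +
                                               0.02 * d^2)), numeric(1))
    curve <- fit_dose_response(tibble::tibble(dose_gy = doses, n_cells = 800,
                                              n_dicentrics = x))
    expect_gte(curve$dispersion_scale, 1)
  }
})

test_that("the envelope collapses and expands as the covariance dictates", {
  flat <- make_curve(vcov = matrix(0, 3, 3))
  env <- curve_envelope(flat, c(0, 1, 2, 4))
  expect_equal(env$lower, env$fit)
  expect_equal(env$upper, env$fit)

  vc <- diag(3) * 1e-4
  curve <- make_curve(vcov = vc)
  at0 <- curve_envelope(curve, 0)
  expect_equal(at0$upper - at0$fit, sqrt(qchisq(0.95, 3)) * sqrt(1e-4))
  at2 <- curve_envelope(curve, 2)
  # radicand 1e-4 * (1 + 4 + 16); cross terms vanish for a diagonal vcov
  expect_equal(at2$upper - at2$fit, sqrt(qchisq(0.95, 3) * 21e-4))
  expect_equal(at2$upper - at2$fit, 0.1281, tolerance = 1e-3)
  # envelope always contains the central curve
  grid <- curve_envelope(curve, seq(0, 6, by = 0.1))
  expect_true(all(grid$lower <= grid$fit & grid$fit <= grid$upper))
})

test_that("forward curve and point-estimate inverse are consistent", {
  curve <- make_curve(vcov = diag(3) * 1e-4)
  d <- seq(0, 4, by = 0.05)
  y <- curve_envelope(curve, d)$fit
  expect_equal(merkle_point_estimate(curve, y), d, tolerance = 1e-9)
})

test_that("coefficient z-comparison matches the closed form", {
  a <- make_curve(alpha = 0.07, vcov = diag(c(1e-4, 4e-4, 1e-4)))
  b <- make_curve(alpha = 0.07, vcov = diag(c(1e-4, 4e-4, 1e-4)))
  cmp <- compare_curves(a, b, "alpha")
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p.value, 1)

  c1 <- make_curve(alpha = 0.10, vcov = diag(c(1e-4, 4e-4, 1e-4)))
  c2 <- make_curve(alpha = 0.04, vcov = diag(c(1e-4, 4e-4, 1e-4)))
  cmp2 <- compare_curves(c1, c2, "alpha")
  expect_equal(cmp2$z, 2.1213, tolerance = 1e-4)
  expect_equal(cmp2$p.value, 0.0339, tolerance = 1e-2)

  z0 <- make_curve(vcov = matrix(0, 3, 3))
  expect_error(compare_curves(z0, z0, "alpha"),
               class = "dcadose_degenerate_data")
})

test_that("confidence intervals cover the truth at close to nominal rate", {
  doses <- c(0, 0.5, 1, 2, 3, 4)
  truth <- c(0.06, 0.07, 0.02)
  set.seed(928)
  covered <- t(replicate(200, {
    x <- vapply(doses, function(d) sum(rpois(2000, truth[1] + truth[2] * d +
                                               truth[3] * d^2)), numeric(1))
    curve <- fit_dose_response(tibble::tibble(dose_gy = doses, n_cells = 2000,
                                              n_dicentrics = x))
    abs(curve$coefficients - truth) <= 1.96 * curve$se
  }))
  rates <- colMeans(covered)
  expect_true(all(rates > 0.90))
})

test_that("tidy and glance expose the fit in broom shape", {
  pts <- tibble::tibble(dose_gy = c(0, 0.5, 1, 2, 3, 4), n_cells = 1000,
                        n_dicentrics = c(55, 104, 151, 273, 462, 655))
  curve <- fit_dose_response(pts)
  td <- tidy(curve)
  expect_identical(td$term, c("C", "alpha", "beta"))
  expect_identical(names(td), c("term", "estimate", "std.error", "statistic",
                                "p.value"))
  gl <- glance(curve)
  expect_identical(gl$n_doses, 6L)
  expect_equal(gl$r2_factor, qchisq(0.95, 3))
  expect_s3_class(autoplot(curve), "ggplot")
})
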