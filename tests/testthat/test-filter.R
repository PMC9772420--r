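test_that("accepted-flag filtering keeps flagged rows and is idempotent", {
  tbl <- make_records(rep(46, 5), accepted = c(TRUE, TRUE, TRUE, FALSE,
                                               FALSE))
  kept <- filter_accepted(tbl)
  expect_identical(nrow(kept), 3L)
  expect_identical(filter_accepted(kept), kept)
  expect_identical(filter_accepted(make_records(46, accepted = TRUE)) |> nrow(),
                   1L)
  expect_identical(nrow(filter_accepted(make_records(rep(46, 3),
                                                     accepted = FALSE))), 0L)
})

test_that("IQR fences follow the linear-interpolation quartile convention", {
  f <- iqr_fences(c(40, 44, 45, 46, 47, 100))
  expect_equal(f$q1, 44.25)
  expect_equal(f$q3, 46.75)
  expect_equal(f$iqr, 2.5)
  expect_equal(f$lower_fence, 40.5)
  expect_equal(f$upper_fence, 50.5)

  f0 <- iqr_fences(rep(46, 5))
  expect_equal(f0$iqr, 0)
  expect_equal(c(f0$lower_fence, f0$upper_fence), c(46, 46))

  f2 <- iqr_fences(c(10, 90))
  expect_equal(c(f2$q1, f2$q3, f2$iqr), c(30, 70, 40))
  expect_equal(c(f2$lower_fence, f2$upper_fence), c(-30, 130))

  expect_error(iqr_fences(46), class = "dcadose_insufficient_data")
})

test_that("fence filtering removes strict outliers and keeps fence values", {
  tbl <- make_records(c(40, 44, 45, 46, 47, 100))
  out <- filter_by_fences(tbl)
  expect_setequal(out$n_chromosomes, c(44, 45, 46, 47))
  rep <- filter_report(out)
  expect_identical(rep$n_input, 6L)
  expect_identical(rep$n_retained, 4L)
  expect_identical(rep$fences$n_excluded_low, 1L)
  expect_identical(rep$fences$n_excluded_high, 1L)

  # constant counts: nothing removed
  const <- filter_by_fences(make_records(rep(46, 5)))
  expect_identical(nrow(const), 5L)

  # counts equal to a fence are retained (zero-IQR makes the fences equal
  # the common value)
  tied <- filter_by_fences(make_records(c(10, 10, 10, 10, 14)))
  expect_identical(sort(tied$n_chromosomes), rep(10L, 4))

  expect_error(filter_by_fences(make_records(46)),
               class = "dcadose_insufficient_data")
})

test_that("per-dose grouping places fences within each dose", {
  tbl <- dplyr::bind_rows(
    make_records(c(40, 44, 45, 46, 47, 100), dose = 1),
    make_records(c(90, 91, 92, 93, 94, 5), dose = 2)
  )
  out <- filter_by_fences(tbl, per_dose = TRUE)
  expect_setequal(out$n_chromosomes[out$dose_gy == 1], c(44, 45, 46, 47))
  expect_setequal(out$n_chromosomes[out$dose_gy == 2], c(90, 91, 92, 93, 94))
  expect_error(
    filter_by_fences(dplyr::bind_rows(make_records(c(40, 44), dose = 1),
                                      make_records(46, dose = 2))),
    "dose", class = "dcadose_insufficient_data")
})

test_that("no record inside the fences is ever removed", {
  recs <- simulate_records(sim_config(cells_per_dose = 300, seed = 8))
  out <- filter_by_fences(recs)
  fences <- filter_report(out)$fences
  for (g in fences$group) {
    f <- fences[fences$group == g, ]
    kept <- out$n_chromosomes[out$dose_gy == as.numeric(g)]
    expect_true(all(kept >= f$lower_fence & kept <= f$upper_fence))
    dropped <- setdiff(
      recs$n_chromosomes[recs$dose_gy == as.numeric(g)], kept)
    expect_true(all(dropped < f$lower_fence | dropped > f$upper_fence))
  }
})

test_that("harmonization strips multi-cell and debris contamination", {
  recs <- simulate_records(default_sim_config(seed = 5))
  out <- harmonize_records(recs)
  rep <- filter_report(out)
  expect_lte(rep$n_retained, rep$n_accepted)
  expect_lte(rep$n_accepted, rep$n_input)
  expect_true(all(out$n_chromosomes > 10))
  expect_true(all(out$n_chromosomes <= 100))
  # a second fence pass removes (almost) nothing compared to the first
  first_frac <- 1 - rep$n_retained / rep$n_accepted
  again <- filter_by_fences(out)
  second_frac <- 1 - nrow(again) / nrow(out)
  expect_lt(second_frac, first_frac)
})

test_that("count summaries report sample statistics per group", {
  s <- summarize_counts(make_records(c(44, 46, 48)))
  expect_equal(s$mean, 46)
  expect_equal(s$median, 46)
  expect_equal(s$sd, 2)
  expect_equal(summarize_counts(make_records(rep(46, 4)))$sd, 0)
  expect_error(summarize_counts(make_records(46)),
               class = "dcadose_insufficient_data")
  expect_error(summarize_counts(make_records(integer(0))),
               class = "dcadose_insufficient_data")
  two <- summarize_counts(dplyr::bind_rows(
    make_records(c(44, 48), donor = "S1"),
    make_records(c(40, 50), donor = "S2")
  ), by = "donor_id")
  expect_identical(nrow(two), 2L)
})
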