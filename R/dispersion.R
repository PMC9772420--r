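#' Dispersion index of per-cell dicentric counts
#'
#' The dispersion index DI is the ratio of the sample variance (n-1
#' denominator) of per-cell dicentric counts to the mean yield; it is 1 in
#' expectation for Poisson counts, the behaviour expected of dicentrics under
#' acute whole-body low-LET exposure.
#'
#' @param counts Integer vector of per-cell dicentric counts (>= 2 cells, at
#'   least one nonzero count).
#' @return One-row tibble: `mean_yield`, `variance`, `di`.
#' @export
#' @examples
#' dispersion_index(c(0, 0, 1, 1, 2))
dispersion_index <- function(counts) {
  counts <- as.double(counts)
  if (length(counts) < 2 || anyNA(counts)) {
    abort_insufficient("need at least 2 non-missing counts.")
  }
  if (all(counts == 0)) {
    abort_degenerate(
      "all counts are zero: DI = variance/mean is undefined at mean 0.")
  }
  m <- mean(counts)
  v <- var(counts)
  tibble(mean_yield = m, variance = v, di = v / m)
}

#' Papworth u-test for Poisson conformity
#'
#' Standardizes the departure of the dispersion index from 1:
#' \deqn{u = (DI - 1)\sqrt{\frac{N-1}{2\,(1 - 1/X)}}}
#' with `N` cells and `X` total dicentrics. Approximately standard normal
#' under the Poisson hypothesis, so `u > 1.96` flags overdispersion and
#' `u < -1.96` underdispersion at the two-sided 5% level.
#'
#' @param counts Integer vector of per-cell dicentric counts; requires
#'   `N >= 2` and total dicentrics `X > 1`.
#' @param threshold Critical value for the verdict (default 1.96, the
#'   two-sided 5% normal quantile).
#' @return One-row tibble: `n_cells`, `total_dicentrics`, `mean_yield`,
#'   `variance`, `di`, `u`, `verdict` (poisson / overdispersed /
#'   underdispersed).
#' @export
#' @examples
#' papworth_u(c(0, 0, 1, 1, 2))
papworth_u <- function(counts, threshold = 1.96) {
  counts <- as.double(counts)
  di <- dispersion_index(counts)
  n <- length(counts)
  x <- sum(counts)
  if (x <= 1) {
    abort_degenerate(
      "Papworth u is undefined for a total dicentric count of 1 or less.")
  }
  u <- (di$di - 1) * sqrt((n - 1) / (2 * (1 - 1 / x)))
  verdict <- if (u > threshold) "overdispersed"
             else if (u < -threshold) "underdispersed"
             else "poisson"
  tibble(
    n_cells = n, total_dicentrics = x,
    mean_yield = di$mean_yield, variance = di$variance, di = di$di,
    u = u, verdict = verdict
  )
}

#' Poisson-conformity table per donor-dose group and pooled per dose
#'
#' Runs the dispersion index and Papworth u-test within every donor-by-dose
#' group and, when `pooled = TRUE`, on each dose pooled across donors.
#' Groups where the statistic is undefined (all-zero counts, or one dicentric
#' in total — typical of unexposed controls) are reported with verdict
#' `"degenerate"` rather than failing the whole table.
#'
#' @param records A validated record table.
#' @param pooled Also test each dose pooled across donors?
#' @param threshold Critical value passed to [papworth_u()].
#' @return Tibble with one row per group: `donor_id` (`"pooled"` for pooled
#'   rows), `dose_gy`, and the [papworth_u()] columns.
#' @export
dispersion_test <- function(records, pooled = TRUE, threshold = 1.96) {
  records <- validate_with_extra(records)
  if (nrow(records) == 0) {
    abort_insufficient("no records to test.")
  }
  one_group <- function(counts, donor, dose) {
    res <- tryCatch(
      papworth_u(counts, threshold = threshold),
      dcadose_error = function(e) {
        tibble(
          n_cells = length(counts), total_dicentrics = sum(counts),
          mean_yield = mean(counts),
          variance = if (length(counts) > 1) var(counts) else NA_real_,
          di = NA_real_, u = NA_real_, verdict = "degenerate"
        )
      }
    )
    dplyr::mutate(res, donor_id = donor, dose_gy = dose, .before = 1)
  }
  per_group <- records |>
    dplyr::group_by(.data$donor_id, .data$dose_gy) |>
    dplyr::group_map(~ one_group(.x$n_dicentrics, .y$donor_id, .y$dose_gy)) |>
    dplyr::bind_rows()
  out <- per_group
  if (pooled) {
    pooled_rows <- records |>
      dplyr::group_by(.data$dose_gy) |>
      dplyr::group_map(~ one_group(.x$n_dicentrics, "pooled", .y$dose_gy)) |>
      dplyr::bind_rows()
    out <- dplyr::bind_rows(per_group, pooled_rows)
  }
  dplyr::arrange(out, .data$donor_id == "pooled", .data$donor_id,
                 .data$dose_gy)
}
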