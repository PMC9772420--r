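#' Keep records the automated scorer flagged "accepted"
#'
#' First stage of the two-step harmonization: drop every image the scorer
#' classified as filtered, preserving row order. Idempotent.
#'
#' @param records A validated record table.
#' @return Tibble of accepted records.
#' @export
filter_accepted <- function(records) {
  records <- validate_with_extra(records)
  records[records$accepted, , drop = FALSE]
}

# validate but keep any extra columns (e.g. the simulator's image_class)
validate_with_extra <- function(records) {
  checked <- validate_records(records)
  extra <- setdiff(names(records), record_columns())
  out <- checked
  for (col in extra) out[[col]] <- records[[col]]
  out
}

#' Tukey fences on chromosome counts
#'
#' Quartiles use the linear-interpolation convention (`stats::quantile`
#' type 7); the fences are `Q1 - k*IQR` and `Q3 + k*IQR` with `k = 1.5` by
#' default. Counts equal to a fence are inside it.
#'
#' @param counts Numeric vector of chromosome counts (at least 2).
#' @param multiplier Fence multiplier `k` (default 1.5; 1.0 gives the
#'   stricter variant).
#' @return One-row tibble: `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`.
#' @export
#' @examples
#' iqr_fences(c(40, 44, 45, 46, 47, 100))
iqr_fences <- function(counts, multiplier = 1.5) {
  counts <- as.double(counts)
  if (length(counts) < 2 || anyNA(counts)) {
    abort_insufficient("need at least 2 non-missing counts to place fences.")
  }
  q <- unname(quantile(counts, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  tibble(
    q1 = q[1], q3 = q[2], iqr = iqr,
    lower_fence = q[1] - multiplier * iqr,
    upper_fence = q[2] + multiplier * iqr
  )
}

#' Exclude chromosome-count outliers beyond the IQR fences
#'
#' Second harmonization stage: removes records whose chromosome count lies
#' strictly below the lower fence or strictly above the upper fence. With
#' `per_dose = TRUE` (the default, matching per-dose pooled calibration
#' analysis) fences are computed within each dose group; otherwise one global
#' pair of fences is used, which suits single-sample estimation input.
#'
#' @param records A validated record table.
#' @param per_dose Compute fences within each dose group?
#' @param multiplier Fence multiplier passed to [iqr_fences()].
#' @return The retained records, with a `"report"` attribute (see
#'   [filter_report()]) holding input/retained tallies and the fences used.
#' @export
filter_by_fences <- function(records, per_dose = TRUE, multiplier = 1.5) {
  records <- validate_with_extra(records)
  n_input <- nrow(records)
  if (per_dose) {
    groups <- split(seq_len(n_input), records$dose_gy)
  } else {
    groups <- list(all = seq_len(n_input))
  }
  fence_rows <- list()
  keep <- logical(n_input)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) < 2) {
      abort_insufficient(paste0(
        "fewer than 2 records in dose group '", g,
        "'; cannot place IQR fences."))
    }
    f <- iqr_fences(records$n_chromosomes[idx], multiplier)
    inside <- records$n_chromosomes[idx] >= f$lower_fence &
      records$n_chromosomes[idx] <= f$upper_fence
    keep[idx] <- inside
    fence_rows[[g]] <- dplyr::mutate(
      f,
      group = g, n_group = length(idx),
      n_excluded_low = sum(records$n_chromosomes[idx] < f$lower_fence),
      n_excluded_high = sum(records$n_chromosomes[idx] > f$upper_fence),
      .before = 1
    )
  }
  out <- records[keep, , drop = FALSE]
  report <- list(
    stage = "iqr_fences",
    n_input = n_input,
    n_retained = nrow(out),
    multiplier = multiplier,
    per_dose = per_dose,
    fences = dplyr::bind_rows(fence_rows)
  )
  attr(out, "report") <- report
  out
}

#' Two-stage quality harmonization: accepted flag, then IQR fences
#'
#' Convenience wrapper applying [filter_accepted()] followed by
#' [filter_by_fences()], returning the harmonized records together with a
#' full filter report (input, accepted and retained counts, per-group fences
#' and exclusion tallies).
#'
#' @inheritParams filter_by_fences
#' @return Retained records with a `"report"` attribute.
#' @export
harmonize_records <- function(records, per_dose = TRUE, multiplier = 1.5) {
  records <- validate_with_extra(records)
  n_input <- nrow(records)
  accepted <- filter_accepted(records)
  out <- filter_by_fences(accepted, per_dose = per_dose,
                          multiplier = multiplier)
  fence_report <- attr(out, "report")
  report <- list(
    n_input = n_input,
    n_accepted = nrow(accepted),
    n_retained = nrow(out),
    excluded_by_flag = n_input - nrow(accepted),
    excluded_by_fences = nrow(accepted) - nrow(out),
    multiplier = multiplier,
    per_dose = per_dose,
    fences = fence_report$fences
  )
  attr(out, "report") <- report
  out
}

#' Retrieve the filter report attached by a filtering stage
#'
#' @param records Output of [filter_by_fences()] or [harmonize_records()].
#' @return The report list, or `NULL` if none is attached.
#' @export
filter_report <- function(records) {
  attr(records, "report")
}

#' Summary statistics of chromosome counts per group
#'
#' Min/mean/median/max and sample standard deviation of the detected
#' chromosome count, grouped by any combination of record columns (per donor
#' or per dose, typically).
#'
#' @param records A validated record table.
#' @param by Character vector of grouping columns (default `donor_id`).
#' @return A tibble with one row per group.
#' @export
summarize_counts <- function(records, by = "donor_id") {
  records <- validate_with_extra(records)
  if (nrow(records) == 0) {
    abort_insufficient("no records to summarize.")
  }
  bad <- setdiff(by, names(records))
  if (length(bad)) {
    abort_input(paste0("unknown grouping column(s): ",
                       paste(bad, collapse = ", ")))
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$n_chromosomes),
      mean = mean(.data$n_chromosomes),
      median = median(.data$n_chromosomes),
      max = max(.data$n_chromosomes),
      sd = sd(.data$n_chromosomes),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    abort_insufficient(
      "a group has a single record; its standard deviation is undefined.")
  }
  out
}
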