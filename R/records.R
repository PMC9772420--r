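#' Per-image scoring record schema
#'
#' A record table holds one row per captured metaphase image as reported by an
#' automated dicentric scorer: the image and donor identifiers, the nominal
#' dose the sample received, the number of chromosomes and dicentrics the
#' scorer detected, and the scorer's accepted/filtered quality flag.
#'
#' @return Character vector of the canonical column names, in order.
#' @export
record_columns <- function() {
  c("image_id", "donor_id", "dose_gy", "n_chromosomes", "n_dicentrics",
    "accepted")
}

#' Validate a table of per-image scoring records
#'
#' Checks the canonical schema and the per-record invariants: counts are
#' non-negative integers, doses are non-negative, no image reports more
#' dicentrics than chromosomes, and image identifiers are unique. Any
#' violation is an error naming the offending rows; invalid records never
#' pass silently into downstream analysis.
#'
#' @param records A data frame of per-image records (see [record_columns()]).
#' @return The validated records as a tibble with canonical column order.
#' @export
#' @examples
#' validate_records(tibble::tibble(
#'   image_id = "img1", donor_id = "S1", dose_gy = 1,
#'   n_chromosomes = 46L, n_dicentrics = 0L, accepted = TRUE
#' ))
validate_records <- function(records) {
  if (!is.data.frame(records)) {
    abort_input("`records` must be a data frame of per-image scoring records.")
  }
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0) {
    abort_input(paste0("records are missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)[record_columns()]

  fail <- function(rows, what) {
    abort_input(paste0(
      what, " (row", if (length(rows) > 1) "s" else "", " ",
      paste(head(rows, 10L), collapse = ", "),
      if (length(rows) > 10) ", ..." else "", ")."
    ))
  }
  bad_int <- function(x) {
    !is.numeric(x) | is.na(x) | x < 0 | (abs(x - round(x)) > 0)
  }

  if (nrow(records) == 0) {
    records$n_chromosomes <- as.integer(records$n_chromosomes)
    records$n_dicentrics <- as.integer(records$n_dicentrics)
    return(records)
  }

  if (!is.numeric(records$dose_gy)) {
    abort_input("`dose_gy` must be numeric (Gy).")
  }
  if (!is.numeric(records$n_chromosomes) || !is.numeric(records$n_dicentrics)) {
    abort_input("`n_chromosomes` and `n_dicentrics` must be integer counts.")
  }
  if (!is.logical(records$accepted) || anyNA(records$accepted)) {
    abort_input("`accepted` must be logical with no missing values.")
  }

  rows <- which(is.na(records$image_id) | records$image_id == "")
  if (length(rows)) fail(rows, "missing image_id")
  rows <- which(duplicated(records$image_id))
  if (length(rows)) fail(rows, "duplicate image_id")
  rows <- which(is.na(records$dose_gy) | records$dose_gy < 0)
  if (length(rows)) fail(rows, "dose_gy must be a non-negative dose in Gy")
  rows <- which(bad_int(records$n_chromosomes))
  if (length(rows)) fail(rows, "n_chromosomes must be a non-negative integer")
  rows <- which(bad_int(records$n_dicentrics))
  if (length(rows)) fail(rows, "n_dicentrics must be a non-negative integer")
  rows <- which(records$n_dicentrics > records$n_chromosomes)
  if (length(rows)) {
    fail(rows, "invariant violated: n_dicentrics must not exceed n_chromosomes")
  }

  records$n_chromosomes <- as.integer(records$n_chromosomes)
  records$n_dicentrics <- as.integer(records$n_dicentrics)
  records$donor_id <- as.character(records$donor_id)
  records$image_id <- as.character(records$image_id)
  records$dose_gy <- as.double(records$dose_gy)
  records
}
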