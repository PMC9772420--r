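#' Read per-image scoring records from CSV
#'
#' The on-disk dialect is plain RFC-4180 CSV with a mandatory header and the
#' canonical columns `image_id, donor_id, dose_gy, n_chromosomes,
#' n_dicentrics, accepted`; the accepted flag is stored as `true`/`false`.
#' Every row is validated against the record invariants on the way in; a
#' malformed row is an error naming it, so no invalid record reaches the
#' analysis stages.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("record file does not exist: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(record_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort_input(paste0("record file is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[record_columns()]

  acc <- tolower(raw$accepted)
  bad <- which(!acc %in% c("true", "false"))
  if (length(bad)) {
    abort_input(paste0("`accepted` must be true/false (row ",
                       paste(head(bad, 10L), collapse = ", "), ")."))
  }
  to_num <- function(x, col) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad)) {
      abort_input(paste0("`", col, "` is not numeric (row ",
                         paste(head(bad, 10L), collapse = ", "), ")."))
    }
    v
  }
  parsed <- tibble(
    image_id = raw$image_id,
    donor_id = raw$donor_id,
    dose_gy = to_num(raw$dose_gy, "dose_gy"),
    n_chromosomes = to_num(raw$n_chromosomes, "n_chromosomes"),
    n_dicentrics = to_num(raw$n_dicentrics, "n_dicentrics"),
    accepted = acc == "true"
  )
  validate_records(parsed)
}

#' Write per-image scoring records to CSV
#'
#' Writes the canonical column order with a header; the accepted flag is
#' encoded as `true`/`false`. Output bytes are deterministic for a given
#' table.
#'
#' @param records A validated record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  out <- records[record_columns()]
  out$accepted <- ifelse(out$accepted, "true", "false")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Persist a fitted calibration curve as a structured text archive
#'
#' The archive is JSON with explicit field names: coefficients, standard
#' errors, t and p values, the full 3x3 variance-covariance matrix, the
#' envelope factor and quasi-Poisson scale, plus provenance metadata (donors,
#' doses, record counts, package version, creation time). Numbers are written
#' at full IEEE precision so a write/read round trip reproduces every
#' coefficient and covariance entry exactly. A text format is deliberate:
#' dosimetry calibration artifacts should be auditable by eye.
#'
#' @param curve A fitted `dc_curve` from [fit_dose_response()].
#' @param path Output path for the JSON archive.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "dc_curve")) {
    abort_input("`curve` must be a fitted dc_curve object.")
  }
  payload <- list(
    format = "dcadose-curve",
    format_version = 1L,
    coefficients = as.list(curve$coefficients),
    std_error = as.list(curve$se),
    statistic = as.list(curve$statistic),
    p_value = as.list(curve$p.value),
    vcov = apply(curve$vcov, 1, as.list),
    r2_factor = curve$r2_factor,
    dispersion_scale = curve$dispersion_scale,
    df_residual = curve$df_residual,
    data = list(
      dose_gy = curve$data$dose_gy,
      n_cells = curve$data$n_cells,
      n_dicentrics = curve$data$n_dicentrics
    ),
    metadata = list(
      donors = curve$donors,
      n_records = curve$n_records,
      package = "dcadose",
      version = as.character(packageVersion("dcadose")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  # 17 significant digits uniquely identify an IEEE double: the archive
  # round-trips bit-for-bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve
#' @return For `read_curve()`: the reconstructed `dc_curve`.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) {
    abort_input(paste0("curve archive does not exist: ", path))
  }
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort_format(paste0("cannot parse curve archive: ",
                                            conditionMessage(e)))
                      })
  if (!identical(payload$format, "dcadose-curve")) {
    abort_format("not a dcadose curve archive (missing format tag).")
  }
  need <- c("coefficients", "std_error", "vcov", "r2_factor")
  missing <- setdiff(need, names(payload))
  if (length(missing)) {
    abort_format(paste0("curve archive is missing block(s): ",
                        paste(missing, collapse = ", ")))
  }
  cf <- unlist(payload$coefficients)[c("C", "alpha", "beta")]
  if (anyNA(cf)) abort_format("curve archive coefficients are incomplete.")
  vc <- payload$vcov
  if (is.list(vc)) vc <- do.call(rbind, lapply(vc, unlist))
  vc <- matrix(as.double(vc), 3, 3,
               dimnames = list(names(cf), names(cf)))
  if (anyNA(vc)) abort_format("curve archive covariance block is incomplete.")
  data <- NULL
  if (!is.null(payload$data)) {
    data <- tibble(
      dose_gy = as.double(payload$data$dose_gy),
      n_cells = as.double(payload$data$n_cells),
      n_dicentrics = as.double(payload$data$n_dicentrics)
    )
    data$yield <- ifelse(data$n_cells > 0,
                         data$n_dicentrics / data$n_cells, NA_real_)
  }
  new_dc_curve(
    coefficients = cf,
    vcov = vc,
    se = unlist(payload$std_error)[names(cf)],
    statistic = unlist(payload$statistic)[names(cf)],
    p.value = unlist(payload$p_value)[names(cf)],
    r2_factor = as.double(payload$r2_factor),
    dispersion_scale = as.double(payload$dispersion_scale %||% NA_real_),
    df_residual = as.double(payload$df_residual %||% NA_real_),
    data = data,
    donors = unlist(payload$metadata$donors),
    n_records = payload$metadata$n_records %||% NA_integer_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a simulation/pipeline configuration file
#'
#' Plain-text YAML with one block per stage; see [run_pipeline()] for the
#' recognized blocks.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("configuration file does not exist: ", path))
  }
  tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_config(paste0("cannot parse configuration: ", conditionMessage(e)))
  })
}
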