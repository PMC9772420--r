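#' Plot a fitted calibration curve with its confidence envelope
#'
#' Per-dose yield points, the central linear-quadratic curve (solid) and the
#' 95% confidence envelope (dashed), the conventional rendering of a
#' dicentric calibration curve.
#'
#' @param object A fitted `dc_curve`.
#' @param max_dose Right edge of the dose axis; defaults to the largest
#'   fitted dose.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dc_curve
#' @export
autoplot.dc_curve <- function(object, max_dose = NULL, ...) {
  max_dose <- max_dose %||% max(object$data$dose_gy)
  grid <- curve_envelope(object, seq(0, max_dose, length.out = 200))
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$dose_gy)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = "Dose (Gy)", y = "Dicentrics per cell",
                  title = "Linear-quadratic dose-response curve",
                  subtitle = "quasi-Poisson fit with 95% envelope")
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(
      data = object$data,
      ggplot2::aes(x = .data$dose_gy, y = .data$yield)
    )
  }
  p
}

#' Chromosome-count distribution per donor
#'
#' Histograms of detected chromosome counts, faceted by donor, to visualize
#' the multi-cell (>100 chromosomes) and debris (<=10) contamination that
#' quality filtering removes.
#'
#' @param records A validated record table.
#' @param binwidth Histogram bin width (chromosomes).
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(records, binwidth = 5) {
  records <- validate_with_extra(records)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$n_chromosomes)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~donor_id) +
    ggplot2::labs(x = "Detected chromosomes per image", y = "Images")
}

#' Plot dose estimates against the calibration curve
#'
#' Overlays blind-sample yield observations (with their exact Poisson limits)
#' on the calibration curve and envelope, with the estimated dose interval
#' projected onto the dose axis.
#'
#' @param curve A fitted `dc_curve`.
#' @param estimates One or more rows from [estimate_dose()] (bind rows for
#'   several samples).
#' @return A ggplot object.
#' @export
plot_dose_estimates <- function(curve, estimates) {
  max_dose <- max(c(curve$data$dose_gy, estimates$dose_upper_gy), na.rm = TRUE)
  p <- autoplot(curve, max_dose = max_dose)
  p +
    ggplot2::geom_segment(
      data = estimates,
      ggplot2::aes(x = ifelse(is.na(.data$dose_lower_gy), 0,
                              .data$dose_lower_gy),
                   xend = .data$dose_upper_gy,
                   y = .data$yield, yend = .data$yield),
      colour = "firebrick"
    ) +
    ggplot2::geom_point(
      data = estimates,
      ggplot2::aes(x = .data$dose_gy, y = .data$yield),
      colour = "firebrick", size = 2
    )
}
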