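#' Aggregate per-image records into per-dose yield points
#'
#' For each dose: the number of scored cells N, the total dicentric count X,
#' and the yield Y = X/N in dicentrics per cell. Input should already be
#' harmonized (see [harmonize_records()]); aggregation is additive, so
#' concatenating two tables sums N and X per dose.
#'
#' @param records A validated record table.
#' @return Tibble of dose points: `dose_gy`, `n_cells`, `n_dicentrics`,
#'   `yield`.
#' @export
aggregate_yields <- function(records) {
  records <- validate_with_extra(records)
  if (nrow(records) == 0) {
    abort_insufficient("no records to aggregate.")
  }
  records |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_dicentrics = sum(.data$n_dicentrics),
      .groups = "drop"
    ) |>
    dplyr::mutate(yield = .data$n_dicentrics / .data$n_cells) |>
    dplyr::arrange(.data$dose_gy)
}

new_dc_curve <- function(coefficients, vcov, se, statistic, p.value,
                         r2_factor, dispersion_scale, df_residual,
                         data = NULL, donors = NULL, n_records = NULL) {
  structure(
    list(
      coefficients = coefficients, vcov = vcov, se = se,
      statistic = statistic, p.value = p.value, r2_factor = r2_factor,
      dispersion_scale = dispersion_scale, df_residual = df_residual,
      data = data, donors = donors, n_records = n_records
    ),
    class = "dc_curve"
  )
}

#' Fit the linear-quadratic dose-response calibration curve
#'
#' Fits \eqn{Y(D) = C + \alpha D + \beta D^2} to per-dose dicentric totals by
#' quasi-Poisson regression with identity link: the count \eqn{X_d} at dose
#' \eqn{D_d} is modelled as Poisson with mean \eqn{N_d\,(C + \alpha D_d +
#' \beta D_d^2)}, which weights each dose by the number of scored cells, the
#' standard formulation for low-LET dicentric calibration. Standard errors
#' use the Pearson-estimated dispersion scale floored at 1, so quasi-Poisson
#' uncertainty is never smaller than the pure Poisson fit's. Coefficient
#' tests are t-statistics on the residual degrees of freedom.
#'
#' @param data Either per-dose points (`dose_gy`, `n_cells`, `n_dicentrics`)
#'   as from [aggregate_yields()], or a per-image record table, which is
#'   aggregated first. At least 4 distinct doses are required for the
#'   3-parameter model.
#' @param r2_factor Confidence-envelope factor \eqn{R^2}; defaults to the
#'   95th percentile of chi-squared with 3 degrees of freedom (7.81).
#' @return A `dc_curve` object; see [tidy.dc_curve()], [glance.dc_curve()],
#'   [curve_envelope()], [autoplot.dc_curve()].
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   dose_gy = c(0, 0.5, 1, 2, 3, 4), n_cells = 1000,
#'   n_dicentrics = c(60, 100, 150, 280, 450, 660)
#' )
#' fit_dose_response(pts)
fit_dose_response <- function(data, r2_factor = qchisq(0.95, df = 3)) {
  if (!is.data.frame(data)) {
    abort_input("`data` must be a data frame.")
  }
  if (all(record_columns() %in% names(data))) {
    points <- aggregate_yields(data)
    donors <- unique(data$donor_id)
    n_records <- nrow(data)
  } else {
    need <- c("dose_gy", "n_cells", "n_dicentrics")
    missing_cols <- setdiff(need, names(data))
    if (length(missing_cols)) {
      abort_input(paste0("dose points need column(s): ",
                         paste(missing_cols, collapse = ", ")))
    }
    points <- dplyr::arrange(as_tibble(data)[need], .data$dose_gy)
    points$yield <- points$n_dicentrics / points$n_cells
    donors <- attr(data, "donors")
    n_records <- sum(points$n_cells)
  }
  if (anyDuplicated(points$dose_gy)) {
    abort_input("duplicate dose points; aggregate per dose first.")
  }
  if (nrow(points) < 4) {
    abort_insufficient(
      "need at least 4 distinct doses to fit the 3-parameter model.")
  }
  if (any(points$n_cells < 1) || any(!is.finite(points$yield))) {
    abort_input("every dose point needs n_cells >= 1 and a finite yield.")
  }

  d <- tibble(
    X = points$n_dicentrics,
    z0 = points$n_cells,
    z1 = points$n_cells * points$dose_gy,
    z2 = points$n_cells * points$dose_gy^2
  )
  # start from cell-weighted least squares on the yields; nudge the intercept
  # positive so the identity-link Poisson fit starts at a valid mean
  ls <- lm(yield ~ dose_gy + I(dose_gy^2), data = points,
           weights = points$n_cells)
  start <- unname(coef(ls))
  start[1] <- max(start[1], 1e-4)
  mu0 <- as.matrix(d[c("z0", "z1", "z2")]) %*% start
  if (any(mu0 <= 0)) start <- c(max(mean(points$yield), 1e-3), 1e-3, 1e-3)

  fit <- tryCatch(
    glm(X ~ 0 + z0 + z1 + z2, family = poisson(link = "identity"),
        data = d, start = start),
    error = function(e) {
      abort_fit(paste0("linear-quadratic fit failed: ", conditionMessage(e)))
    }
  )
  if (!fit$converged) {
    abort_fit("linear-quadratic fit did not converge.")
  }
  if (any(fitted(fit) <= 0)) {
    abort_fit("fitted mean is non-positive at an observed dose.")
  }

  est <- setNames(unname(coef(fit)), c("C", "alpha", "beta"))
  dfres <- df.residual(fit)
  pearson <- sum(residuals(fit, type = "pearson")^2) / dfres
  scale <- max(1, pearson)
  vc <- summary(fit)$cov.unscaled * scale
  dimnames(vc) <- list(names(est), names(est))
  se <- sqrt(diag(vc))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = dfres)

  new_dc_curve(
    coefficients = est, vcov = vc, se = se, statistic = tval, p.value = pval,
    r2_factor = r2_factor, dispersion_scale = scale, df_residual = dfres,
    data = points, donors = donors, n_records = n_records
  )
}

#' Evaluate the fitted curve
#'
#' @param object A `dc_curve`.
#' @param newdata Optional tibble with a `dose_gy` column, or a numeric dose
#'   vector; defaults to the fitted doses.
#' @param ... Unused.
#' @return Numeric vector of yields (dicentrics/cell).
#' @export
predict.dc_curve <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose_gy
          else if (is.numeric(newdata)) newdata
          else newdata$dose_gy
  cf <- object$coefficients
  unname(cf["C"] + cf["alpha"] * dose + cf["beta"] * dose^2)
}

#' 95% confidence envelope of the calibration curve
#'
#' The envelope around the fitted yield at dose D has half-width
#' \deqn{R\sqrt{\mathrm{var}C + \mathrm{var}\alpha D^2 + \mathrm{var}\beta D^4
#'   + 2\mathrm{cov}(C,\alpha)D + 2\mathrm{cov}(C,\beta)D^2
#'   + 2\mathrm{cov}(\alpha,\beta)D^3}}
#' with \eqn{R^2} the envelope factor stored in the curve (default: the 95th
#' percentile of chi-squared with 3 df, 7.81). The radicand is the quadratic
#' form \eqn{(1, D, D^2)\,V\,(1, D, D^2)^\top} and is non-negative for any
#' valid covariance matrix.
#'
#' @param curve A fitted `dc_curve`.
#' @param dose Numeric vector of non-negative doses in Gy.
#' @return Tibble: `dose_gy`, `lower`, `fit`, `upper` (dicentrics/cell).
#' @export
curve_envelope <- function(curve, dose) {
  if (!inherits(curve, "dc_curve")) {
    abort_input("`curve` must be a fitted dc_curve.")
  }
  dose <- as.double(dose)
  if (anyNA(dose) || any(dose < 0)) {
    abort_input("`dose` must be non-negative (Gy).")
  }
  v <- curve$vcov
  central <- predict(curve, dose)
  radicand <- v["C", "C"] + v["alpha", "alpha"] * dose^2 +
    v["beta", "beta"] * dose^4 +
    2 * v["C", "alpha"] * dose + 2 * v["C", "beta"] * dose^2 +
    2 * v["alpha", "beta"] * dose^3
  if (any(radicand < -1e-12)) {
    abort_numeric(
      "negative envelope radicand: covariance matrix is not valid.")
  }
  half <- sqrt(curve$r2_factor) * sqrt(pmax(radicand, 0))
  tibble(dose_gy = dose, lower = central - half, fit = central,
         upper = central + half)
}

#' Compare a coefficient between two fitted curves by z-test
#'
#' \eqn{z = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}} with a two-sided normal
#' p-value, the standard check that two donors' calibration curves can be
#' pooled.
#'
#' @param curve_a,curve_b Fitted `dc_curve` objects.
#' @param coefficient One or more of `"C"`, `"alpha"`, `"beta"` (default:
#'   `alpha` and `beta`, the dose-dependent terms).
#' @return Tibble: `coefficient`, `estimate_a`, `estimate_b`, `z`, `p.value`.
#' @export
compare_curves <- function(curve_a, curve_b,
                           coefficient = c("alpha", "beta")) {
  if (!inherits(curve_a, "dc_curve") || !inherits(curve_b, "dc_curve")) {
    abort_input("both arguments must be fitted dc_curve objects.")
  }
  coefficient <- match.arg(coefficient, c("C", "alpha", "beta"),
                           several.ok = TRUE)
  purrr::map_dfr(coefficient, function(k) {
    se <- sqrt(curve_a$se[k]^2 + curve_b$se[k]^2)
    if (se == 0) {
      abort_degenerate("combined standard error is zero; z is undefined.")
    }
    z <- unname((curve_a$coefficients[k] - curve_b$coefficients[k]) / se)
    tibble(
      coefficient = k,
      estimate_a = unname(curve_a$coefficients[k]),
      estimate_b = unname(curve_b$coefficients[k]),
      z = z,
      p.value = 2 * pnorm(-abs(z))
    )
  })
}

#' @export
print.dc_curve <- function(x, ...) {
  cat("Linear-quadratic dicentric dose-response curve\n")
  cat("  Y(D) = C + alpha*D + beta*D^2   [dicentrics/cell]\n\n")
  print(tidy(x), n = 3)
  cat(sprintf("\nquasi-Poisson scale %.3f on %g residual df; envelope factor %.2f\n",
              x$dispersion_scale, x$df_residual, x$r2_factor))
  invisible(x)
}

#' Tidy a fitted calibration curve
#'
#' @param x A `dc_curve`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy dc_curve
#' @export
tidy.dc_curve <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$statistic),
    p.value = unname(x$p.value)
  )
}

#' One-row model summary of a fitted calibration curve
#'
#' @param x A `dc_curve`.
#' @param ... Unused.
#' @return Tibble: `n_doses`, `n_cells`, `dispersion_scale`, `df.residual`,
#'   `r2_factor`.
#' @method glance dc_curve
#' @export
glance.dc_curve <- function(x, ...) {
  tibble(
    n_doses = if (is.null(x$data)) NA_integer_ else nrow(x$data),
    n_cells = if (is.null(x$data)) NA_real_ else sum(x$data$n_cells),
    dispersion_scale = x$dispersion_scale,
    df.residual = x$df_residual,
    r2_factor = x$r2_factor
  )
}
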