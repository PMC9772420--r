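#' Exact (Garwood) Poisson confidence limits on a count's mean
#'
#' Chi-squared closed form for an observed count x:
#' lower = qchisq((1-level)/2, 2x)/2 (0 when x = 0),
#' upper = qchisq(1-(1-level)/2, 2(x+1))/2. These are the conservative exact
#' limits used for the observed dicentric count of a blind sample.
#'
#' @param x Non-negative integer count(s).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Tibble: `x`, `lower_mean`, `upper_mean`.
#' @export
#' @examples
#' poisson_exact_ci(c(0, 10))
poisson_exact_ci <- function(x, level = 0.95) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) ||
      any(abs(x - round(x)) > 0)) {
    abort_input("`x` must be non-negative integer count(s).")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort_input("`level` must be strictly between 0 and 1.")
  }
  a <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, qchisq(a, df = 2 * x) / 2)
  upper <- qchisq(1 - a, df = 2 * (x + 1)) / 2
  tibble(x = as.double(x), lower_mean = lower, upper_mean = upper)
}

#' Observed dicentric yield with exact Poisson limits
#'
#' @param n_cells Number of scored cells N.
#' @param n_dicentrics Observed dicentric count X.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `n_cells`, `n_dicentrics`, `yield`, `yield_lower`,
#'   `yield_upper` (the exact limits on the mean count divided by N).
#' @export
yield_observation <- function(n_cells, n_dicentrics, level = 0.95) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1) {
    abort_input("`n_cells` must be a single count >= 1.")
  }
  ci <- poisson_exact_ci(n_dicentrics, level)
  tibble(
    n_cells = as.double(n_cells),
    n_dicentrics = as.double(n_dicentrics),
    yield = n_dicentrics / n_cells,
    yield_lower = ci$lower_mean / n_cells,
    yield_upper = ci$upper_mean / n_cells
  )
}

#' Invert the calibration curve: yield to point dose
#'
#' Positive root of the linear-quadratic curve,
#' \eqn{D = (-\alpha + \sqrt{\alpha^2 + 4\beta(Y - C)})/(2\beta)}. A yield at
#' or below the background C maps to dose 0 (flagged below background by
#' [estimate_dose()]); a zero beta falls back to the linear inverse
#' \eqn{(Y - C)/\alpha}.
#'
#' @param curve A fitted `dc_curve`.
#' @param y Observed yield(s), dicentrics per cell.
#' @return Numeric dose(s) in Gy.
#' @export
#' @examples
#' \dontrun{merkle_point_estimate(curve, 0.28)}
merkle_point_estimate <- function(curve, y) {
  if (!inherits(curve, "dc_curve")) {
    abort_input("`curve` must be a fitted dc_curve.")
  }
  if (!is.numeric(y) || anyNA(y)) abort_input("`y` must be finite yields.")
  cf <- curve$coefficients
  invert_lq(unname(cf["C"]), unname(cf["alpha"]), unname(cf["beta"]), y)
}

invert_lq <- function(C, alpha, beta, y) {
  out <- numeric(length(y))
  below <- y <= C
  out[below] <- 0
  yy <- y[!below]
  if (length(yy)) {
    if (beta == 0) {
      if (alpha == 0) {
        abort_numeric("flat curve (alpha = beta = 0) cannot be inverted.")
      }
      out[!below] <- (yy - C) / alpha
    } else {
      disc <- alpha^2 + 4 * beta * (yy - C)
      if (any(disc < 0)) {
        abort_numeric("no real dose solves the curve for this yield.")
      }
      out[!below] <- (-alpha + sqrt(disc)) / (2 * beta)
    }
  }
  out
}

#' Triage category of an estimated dose
#'
#' Coarse clinical triage bins for acute whole-body exposure: up to 1 Gy,
#' then 1-2, 2-4, 4-6 and above 6 Gy. Bins are closed on the right (a dose of
#' exactly 6 Gy is "4-6").
#'
#' @param dose Non-negative dose(s) in Gy.
#' @return Character vector with levels `<1`, `1-2`, `2-4`, `4-6`, `>6`.
#' @export
#' @examples
#' triage_category(c(0.4, 3, 6))
triage_category <- function(dose) {
  if (!is.numeric(dose) || anyNA(dose) || any(dose < 0)) {
    abort_input("`dose` must be non-negative (Gy).")
  }
  as.character(cut(dose, breaks = c(0, 1, 2, 4, 6, Inf),
                   labels = c("<1", "1-2", "2-4", "4-6", ">6"),
                   include.lowest = TRUE, right = TRUE))
}

# bisection on [lo, hi] for f with f(lo), f(hi) of opposite sign
bisect_root <- function(f, lo, hi, tol = 1e-6, maxit = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) {
    abort_numeric("bisection bracket does not straddle a sign change.")
  }
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Find the dose where the chosen envelope bound equals `target` yield.
# side "lower": rising lower-envelope curve (used for the upper dose limit);
# side "upper": rising upper-envelope curve (used for the lower dose limit).
# Returns NA when the target lies below the bound's minimum over D >= 0
# (non-intersection), a genuine outcome for low-count observations.
solve_envelope_dose <- function(curve, target, side = c("lower", "upper"),
                                d_cap = 20, tol = 1e-6) {
  side <- match.arg(side)
  bound <- function(d) {
    env <- curve_envelope(curve, d)
    if (side == "lower") env$lower else env$upper
  }
  g <- function(d) bound(d) - target

  hi <- 1
  while (g(hi) < 0 && hi < d_cap) hi <- min(2 * hi, d_cap)
  if (g(hi) < 0) {
    abort_numeric(paste0(
      "envelope never reaches the target yield below ", d_cap, " Gy."))
  }
  if (g(0) <= 0) {
    return(bisect_root(g, 0, hi, tol = tol))
  }
  # bound starts above the target: intersection exists only if the envelope
  # dips below it somewhere (possible with strong negative covariances)
  opt <- optimize(g, c(0, hi))
  if (opt$objective > 0) {
    return(NA_real_)
  }
  bisect_root(g, opt$minimum, hi, tol = tol)
}

#' Estimate absorbed dose with 95% confidence limits and triage category
#'
#' Merkle's method: the point dose inverts the central curve at the observed
#' yield; the upper dose limit is the dose at which the lower envelope curve
#' reaches the upper exact-Poisson yield limit, and the lower dose limit the
#' dose at which the upper envelope curve reaches the lower yield limit.
#' Intersections are solved by bisection (tolerance 1e-6 Gy) with the search
#' bracket auto-extended up to 20 Gy. When the lower yield limit lies below
#' the upper envelope everywhere on D >= 0 — typical of low-count,
#' low-dose observations — the lower dose limit is `NA`.
#'
#' @param curve A fitted `dc_curve`.
#' @param n_cells Number of scored cells in the blind sample.
#' @param n_dicentrics Observed dicentric count.
#' @param level Confidence level for the count limits (default 0.95, the
#'   level the envelope factor also encodes).
#' @return A `dc_dose_estimate`: one-row tibble with the yield observation,
#'   `dose_gy`, `dose_lower_gy` (possibly `NA`), `dose_upper_gy`,
#'   `below_background` and `triage_category`.
#' @export
#' @examples
#' \dontrun{estimate_dose(curve, n_cells = 500, n_dicentrics = 140)}
estimate_dose <- function(curve, n_cells, n_dicentrics, level = 0.95) {
  if (!inherits(curve, "dc_curve")) {
    abort_input("`curve` must be a fitted dc_curve.")
  }
  obs <- yield_observation(n_cells, n_dicentrics, level)
  point <- merkle_point_estimate(curve, obs$yield)
  below <- obs$yield <= unname(curve$coefficients["C"])

  upper <- solve_envelope_dose(curve, obs$yield_upper, side = "lower")
  if (is.na(upper)) {
    # lower envelope exceeds even the upper yield limit everywhere; the
    # whole observation is below the curve's resolving power
    upper <- 0
  }
  lower <- solve_envelope_dose(curve, obs$yield_lower, side = "upper")

  out <- dplyr::mutate(
    obs,
    dose_gy = point,
    dose_lower_gy = lower,
    dose_upper_gy = upper,
    below_background = below,
    triage_category = triage_category(point)
  )
  class(out) <- c("dc_dose_estimate", class(out))
  out
}

#' Tidy a dose estimate
#'
#' @param x A `dc_dose_estimate`.
#' @param ... Unused.
#' @return The estimate as a plain tibble.
#' @method tidy dc_dose_estimate
#' @export
tidy.dc_dose_estimate <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dc_dose_estimate")
  out
}

#' @export
print.dc_dose_estimate <- function(x, ...) {
  cat(sprintf(
    "Dose estimate: %.2f Gy (95%% CI %s - %.2f), triage %s\n",
    x$dose_gy,
    ifelse(is.na(x$dose_lower_gy), "NA", sprintf("%.2f", x$dose_lower_gy)),
    x$dose_upper_gy, x$triage_category))
  cat(sprintf("  observed %g dicentrics in %g cells (yield %.4f, CI %.4f - %.4f)\n",
              x$n_dicentrics, x$n_cells, x$yield, x$yield_lower,
              x$yield_upper))
  if (x$below_background) cat("  yield at or below curve background\n")
  invisible(x)
}
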