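# Shared fixtures: records built in code and hand-assembled curves.

make_records <- function(n_chrom, dic = 0, dose = 1, donor = "S1",
                         accepted = TRUE) {
  n <- length(n_chrom)
  tibble::tibble(
    image_id = sprintf("%s-img%03d-%04.1f", donor, seq_len(n), dose),
    donor_id = rep_len(donor, n),
    dose_gy = rep_len(dose, n),
    n_chromosomes = as.integer(n_chrom),
    n_dicentrics = as.integer(rep_len(dic, n)),
    accepted = rep_len(accepted, n)
  )
}

# curve object with chosen coefficients and covariance, bypassing the fit
make_curve <- function(C = 0.06, alpha = 0.07, beta = 0.02,
                       vcov = matrix(0, 3, 3),
                       r2_factor = qchisq(0.95, df = 3)) {
  nm <- c("C", "alpha", "beta")
  dimnames(vcov) <- list(nm, nm)
  est <- c(C = C, alpha = alpha, beta = beta)
  se <- sqrt(diag(vcov))
  dcadose:::new_dc_curve(
    coefficients = est, vcov = vcov, se = se,
    statistic = ifelse(se > 0, est / se, NA_real_),
    p.value = rep(NA_real_, 3),
    r2_factor = r2_factor, dispersion_scale = 1, df_residual = 3,
    data = NULL
  )
}

# random plausible calibration curve with a positive-definite covariance of
# realistic magnitude (used for the envelope-intersection oracle checks)
random_curve <- function() {
  sds <- c(runif(1, 0.002, 0.008), runif(1, 0.002, 0.015),
           runif(1, 0.0005, 0.002))
  B <- matrix(rnorm(9), 3)
  corr <- stats::cov2cor(B %*% t(B))
  make_curve(
    C = runif(1, 0.01, 0.1),
    alpha = runif(1, 0.01, 0.15),
    beta = runif(1, 0.01, 0.05),
    vcov = diag(sds) %*% corr %*% diag(sds)
  )
}

# brute-force fine-grid oracle for the envelope/yield intersections
grid_oracle_limits <- function(curve, yield_lower, yield_upper,
                               d_max = 20, n_grid = 1e4) {
  d <- seq(0, d_max, length.out = n_grid + 1)
  env <- curve_envelope(curve, d)
  upper_idx <- which(env$lower >= yield_upper)[1]
  upper <- if (is.na(upper_idx)) NA_real_ else d[upper_idx]
  if (yield_lower < min(env$upper)) {
    lower <- NA_real_
  } else {
    lower_idx <- which(env$upper >= yield_lower)[1]
    lower <- d[lower_idx]
  }
  list(lower = lower, upper = upper)
}

papworth_reject <- function(counts, threshold = 1.96) {
  res <- papworth_u(counts, threshold = threshold)
  abs(res$u) > threshold
}
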