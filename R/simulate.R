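#' Simulation configuration for synthetic automated-scoring output
#'
#' Describes the ground truth and image-quality artifact structure used by
#' [simulate_records()]. Clean metaphase images carry Poisson-distributed
#' dicentric counts under the linear-quadratic yield curve
#' \eqn{Y(D) = C + \alpha D + \beta D^2}; two artifact classes contaminate the
#' stream the way an automated scanner does: multi-cell captures (two
#' metaphases in one frame, so roughly doubled chromosome and dicentric
#' counts) and debris images (few detected chromosomes, with dose-independent
#' spurious dicentric calls from misidentified chromatin).
#'
#' @param true_curve Named numeric of length 3, `c(C, alpha, beta)` in
#'   dicentrics/cell, /Gy and /Gy^2.
#' @param doses Numeric vector of non-negative doses in Gy.
#' @param cells_per_dose Number of images generated per donor per dose.
#' @param donors Character vector of donor identifiers.
#' @param frac_multicell,frac_debris Proportions of multi-cell and debris
#'   images among all captures; their sum must be below 1.
#' @param false_dicentric_rate Expected spurious dicentric calls per debris
#'   image (Poisson mean, dose-independent).
#' @param chrom_mean,chrom_sd Mean and spread of the detected chromosome count
#'   for a clean single-cell metaphase image.
#' @param accept_model Named numeric probabilities that the scorer flags an
#'   image "accepted", by class `clean`, `multicell`, `debris`.
#' @param seed Integer seed; all randomness in [simulate_records()] flows from
#'   this single value.
#' @return A `dc_sim_config` list.
#' @seealso [default_sim_config()] for the calibration-study defaults.
#' @export
sim_config <- function(true_curve = c(C = 0.06, alpha = 0.07, beta = 0.02),
                       doses = c(0, 0.5, 1, 2, 3, 4),
                       cells_per_dose = 1000L,
                       donors = c("S1", "S2"),
                       frac_multicell = 0.05,
                       frac_debris = 0.08,
                       false_dicentric_rate = 2,
                       chrom_mean = 46,
                       chrom_sd = 9.75,
                       accept_model = c(clean = 0.9, multicell = 0.2,
                                        debris = 0.1),
                       seed = 1L) {
  true_curve <- as.double(true_curve)
  if (length(true_curve) != 3 || anyNA(true_curve)) {
    abort_config("`true_curve` must be three finite values (C, alpha, beta).")
  }
  names(true_curve) <- c("C", "alpha", "beta")
  doses <- as.double(doses)
  if (length(doses) == 0 || anyNA(doses) || any(doses < 0)) {
    abort_config("`doses` must be non-negative values in Gy.")
  }
  yields <- true_curve[1] + true_curve[2] * doses + true_curve[3] * doses^2
  if (any(yields < 0)) {
    abort_config("`true_curve` gives a negative yield on the dose range.")
  }
  cells_per_dose <- as.integer(cells_per_dose)
  if (is.na(cells_per_dose) || cells_per_dose < 0) {
    abort_config("`cells_per_dose` must be a non-negative integer.")
  }
  if (!is.numeric(frac_multicell) || !is.numeric(frac_debris) ||
      frac_multicell < 0 || frac_debris < 0 ||
      frac_multicell + frac_debris >= 1) {
    abort_config("artifact fractions must be >= 0 with sum below 1.")
  }
  if (!is.numeric(false_dicentric_rate) || false_dicentric_rate < 0) {
    abort_config("`false_dicentric_rate` must be non-negative.")
  }
  if (!is.numeric(chrom_mean) || chrom_mean <= 0 ||
      !is.numeric(chrom_sd) || chrom_sd < 0) {
    abort_config("`chrom_mean` must be positive and `chrom_sd` non-negative.")
  }
  accept_model <- accept_model[c("clean", "multicell", "debris")]
  if (anyNA(accept_model) || any(accept_model < 0) || any(accept_model > 1)) {
    abort_config(
      "`accept_model` needs probabilities for clean, multicell and debris.")
  }
  structure(
    list(
      true_curve = true_curve, doses = doses,
      cells_per_dose = cells_per_dose, donors = as.character(donors),
      frac_multicell = frac_multicell, frac_debris = frac_debris,
      false_dicentric_rate = false_dicentric_rate,
      chrom_mean = chrom_mean, chrom_sd = chrom_sd,
      accept_model = accept_model, seed = as.integer(seed)
    ),
    class = "dc_sim_config"
  )
}

#' Default configuration emulating the two-donor calibration study
#'
#' Ground-truth curve (C, alpha, beta) = (0.06, 0.07, 0.02) dicentrics/cell,
#' doses 0, 0.5, 1, 2, 3 and 4 Gy for two donors, clean chromosome counts
#' centred on 46 with spread 9.75, and artifact fractions chosen so the
#' unfiltered chromosome-count distribution has mean about 45 and standard
#' deviation about 18 while accepted-and-harmonized dicentric counts stay
#' Poisson.
#'
#' @param seed Integer seed (default 1).
#' @return A `dc_sim_config` list; calling twice with the same seed gives
#'   identical configurations.
#' @export
default_sim_config <- function(seed = 1L) {
  sim_config(seed = seed)
}

#' @export
print.dc_sim_config <- function(x, ...) {
  cat("<dc_sim_config>\n")
  cat(sprintf("  true curve: C=%g + %g D + %g D^2 (dicentrics/cell)\n",
              x$true_curve[1], x$true_curve[2], x$true_curve[3]))
  cat(sprintf("  doses (Gy): %s | %d cells/dose x %d donor(s)\n",
              paste(x$doses, collapse = ", "), x$cells_per_dose,
              length(x$donors)))
  cat(sprintf("  artifacts: %.0f%% multicell, %.0f%% debris (false rate %g)\n",
              100 * x$frac_multicell, 100 * x$frac_debris,
              x$false_dicentric_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Chromosome count of one clean metaphase: rounded normal truncated at 1.
# The spread models detector miscounting, not biology.
draw_clean_chrom <- function(n, mean, sd) {
  pmax(1L, as.integer(round(rnorm(n, mean, sd))))
}

#' Generate synthetic per-image scoring records
#'
#' Draws `cells_per_dose` image records per donor per dose. Each image is
#' clean, multi-cell or debris with the configured probabilities. Clean images
#' draw chromosome counts from a rounded truncated-normal and dicentric counts
#' from Poisson(Y(D)); multi-cell images are the sum of two independent clean
#' cells; debris images carry at most 10 chromosomes and dose-independent
#' spurious dicentrics. The accepted flag is Bernoulli per class. Every record
#' satisfies `n_dicentrics <= n_chromosomes`, and output is bit-identical for
#' a given seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#' @return A tibble of validated records plus an `image_class` column
#'   (clean/multicell/debris) recording the latent class, which real scorer
#'   output would not contain.
#' @export
#' @examples
#' simulate_records(sim_config(cells_per_dose = 5, seed = 7))
simulate_records <- function(config, seed = NULL) {
  if (!inherits(config, "dc_sim_config")) {
    abort_config("`config` must be created by sim_config().")
  }
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  grid <- tidyr::expand_grid(donor_id = config$donors,
                             dose_gy = config$doses)
  n_per <- config$cells_per_dose
  n <- nrow(grid) * n_per
  if (n == 0) {
    out <- tibble(image_id = character(), donor_id = character(),
                  dose_gy = double(), n_chromosomes = integer(),
                  n_dicentrics = integer(), accepted = logical(),
                  image_class = character())
    return(out)
  }

  set.seed(seed)
  donor <- rep(grid$donor_id, each = n_per)
  dose <- rep(grid$dose_gy, each = n_per)
  tc <- config$true_curve
  yield <- tc[1] + tc[2] * dose + tc[3] * dose^2

  u <- runif(n)
  cls <- ifelse(u < config$frac_debris, "debris",
                ifelse(u < config$frac_debris + config$frac_multicell,
                       "multicell", "clean"))

  chrom <- integer(n)
  dic <- integer(n)

  i <- cls == "clean"
  chrom[i] <- draw_clean_chrom(sum(i), config$chrom_mean, config$chrom_sd)
  dic[i] <- pmin(rpois(sum(i), yield[i]), chrom[i])

  i <- cls == "multicell"
  if (any(i)) {
    chrom[i] <- draw_clean_chrom(sum(i), config$chrom_mean, config$chrom_sd) +
      draw_clean_chrom(sum(i), config$chrom_mean, config$chrom_sd)
    dic[i] <- pmin(rpois(sum(i), yield[i]) + rpois(sum(i), yield[i]), chrom[i])
  }

  i <- cls == "debris"
  if (any(i)) {
    chrom[i] <- sample(0:10, sum(i), replace = TRUE)
    dic[i] <- pmin(rpois(sum(i), config$false_dicentric_rate), chrom[i])
  }

  p_accept <- unname(config$accept_model[cls])
  accepted <- runif(n) < p_accept

  out <- tibble(
    image_id = sprintf("%s-%03.1fGy-%06d", donor, dose,
                       stats::ave(seq_len(n), donor, dose, FUN = seq_along)),
    donor_id = donor,
    dose_gy = dose,
    n_chromosomes = chrom,
    n_dicentrics = dic,
    accepted = accepted,
    image_class = cls
  )
  validate_records(out[record_columns()])
  out
}
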