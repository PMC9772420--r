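---
title: "Dose estimation from automated dicentric scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose estimation from automated dicentric scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcadose)
```

## The problem

After an uncontrolled radiation exposure, the absorbed dose must be
estimated from biology when no physical dosimeter was present. The dicentric
chromosome assay does this by scoring metaphase spreads from cultured
peripheral blood lymphocytes: dicentric chromosomes — aberrant chromosomes
with two centromeres, produced when radiation-induced double-strand breaks
are misrepaired — occur at a very low background rate and accumulate with
dose. For acute whole-body exposure to sparsely ionizing (low-LET)
radiation, the per-cell dicentric count is Poisson distributed and its mean
follows a linear-quadratic dose response.

Deep-learning scorers can process thousands of captured images per sample,
but unlike a human scorer they do not restrict attention to complete,
well-spread metaphases with 46 chromosomes. Their raw output mixes three
image populations:

* **clean** single-cell metaphases, where the dicentric count is the signal;
* **multi-cell captures**, where two metaphases share a frame and both
  chromosome and dicentric counts are roughly doubled;
* **debris** images — cells not in metaphase, or chromatin of poor shape —
  where the detector finds few "chromosomes" and occasionally miscalls
  structures as dicentrics, independent of dose.

The artifact classes inflate the variance of the per-cell dicentric count
above its Poisson mean (overdispersion), which invalidates both the
calibration fit and the dose confidence limits. The pipeline in this package
harmonizes the image stream first and verifies Poisson behaviour before any
curve is fitted.

## Harmonization

Two stages, in fixed order:

1. keep only images the scorer itself flagged *accepted*
   (`filter_accepted()`);
2. exclude chromosome-count outliers beyond the Tukey fences
   `Q1 − k·IQR` and `Q3 + k·IQR` (`filter_by_fences()`), with `k = 1.5` by
   default and a `multiplier` argument for the stricter `k = 1` variant.

Quartiles use the linear-interpolation convention (`stats::quantile`
type 7). No single convention is canonical for small samples and fence
membership changes with the choice, so one is fixed for reproducibility.
Counts exactly equal to a fence are retained — the exclusion rule is for
counts strictly *below* or *above* the fences. Fences are computed within
each dose group by default, because chromosome-count location and spread can
drift with dose; a global mode exists for single-sample estimation input,
where there is no dose structure.

Harmonization is not idempotent in the strict sense (removing outliers moves
the quartiles), but a second fence pass removes at most a sliver of the
data; the test suite asserts the second-pass exclusion fraction is below the
first.

## Poisson conformity

For per-cell counts with mean yield `ȳ`, sample variance `σ²` (n−1
denominator) and total count `X` over `N` cells:

* dispersion index `DI = σ²/ȳ`, equal to 1 in expectation under Poisson;
* Papworth's standardized statistic
  `u = (DI − 1)·√((N−1) / (2(1 − 1/X)))`, approximately standard normal
  under the Poisson hypothesis.

`|u| > 1.96` flags departure at the two-sided 5% level; the threshold is the
field's fixed verdict rule and is kept as the default (an argument allows
overrides). The sample variance, not the population variance, keeps
`E[DI] = 1` at finite `N`. Groups where the statistic is undefined — all
zeros, or a single dicentric in total, both typical of unexposed controls —
are reported with a `degenerate` verdict rather than failing the analysis.

## Calibration curve

The yield is modelled as `Y(D) = C + αD + βD²` with `C` the background yield
(dicentrics/cell), `α` the linear coefficient (/Gy) and `β` the quadratic
coefficient (/Gy²). The fit is a generalized linear model with Poisson
family and identity link on the per-dose totals: the count `X_d` has mean
`N_d · Y(D_d)`, so doses with more scored cells carry proportionally more
weight. The identity link is deliberate — the model is additive on the yield
scale, and a log link would fit a different (multiplicative) model.

Uncertainty is quasi-Poisson: the model covariance is scaled by the Pearson
dispersion estimate, floored at 1. The floor means a run of slightly
underdispersed points (common with only a handful of dose points) can never
shrink the standard errors below the pure Poisson fit's. Coefficient tests
are t-statistics on the residual degrees of freedom (number of dose points
minus 3), the small-sample convention for GLM summaries. At least four
distinct doses are required; a fit whose predicted mean is non-positive at
any observed dose is rejected as an error rather than silently constrained.

The 95% confidence envelope at dose `D` has half-width

```
R · sqrt(varC + varα·D² + varβ·D⁴ + 2cov(C,α)·D + 2cov(C,β)·D² + 2cov(α,β)·D³)
```

where `R² = χ²₀.₉₅(3 df) = 7.81` by default (three fitted parameters). The
radicand is the quadratic form `(1, D, D²) V (1, D, D²)ᵀ` and therefore
non-negative for any valid covariance matrix; a negative radicand is treated
as a numerical-integrity error, not clamped silently.

Two donors' curves are compared coefficient-wise with
`z = (b₁ − b₂)/√(SE₁² + SE₂²)` and a two-sided normal p-value
(`compare_curves()`); pooling their records is justified when neither α nor
β differs.

## Dose estimation (Merkle's method)

For a blind sample with `X` dicentrics in `N` cells:

* The observed yield `Y = X/N` inverts the central curve in closed form,
  `D = (−α + √(α² + 4β(Y − C)))/(2β)`. A yield at or below the background
  `C` maps to dose 0 with a below-background flag — still a usable triage
  outcome — and `β = 0` falls back to the linear inverse.
* The count's exact 95% limits are Garwood's chi-squared bounds,
  `[½χ²₍₀.₀₂₅₎(2X), ½χ²₍₀.₉₇₅₎(2X+2)]` (lower limit 0 at `X = 0`), chosen
  over mid-p variants for conservatism. Divided by `N` they give the yield
  limits.
* The **upper dose limit** is the dose where the *lower* envelope curve
  reaches the upper yield limit; the **lower dose limit** is the dose where
  the *upper* envelope curve reaches the lower yield limit. Because the
  envelope is not a polynomial, these intersections are solved numerically:
  bisection to 1e−6 Gy on a bracket that doubles from 1 Gy and is capped at
  20 Gy, far above any dose the curve is calibrated for. When the lower
  yield limit lies below the minimum of the upper envelope over `D ≥ 0`
  (checked with a continuous minimizer before declaring non-intersection),
  the lower dose limit is reported as `NA` — the expected outcome for
  low-count, low-dose samples whose yield cannot be distinguished from the
  curve's uncertainty at zero dose.

The point estimate is binned into triage categories `<1, 1–2, 2–4, 4–6, >6`
Gy. Bins are closed on the right (a dose of exactly 2 Gy is "1–2"); the
boundary convention is arbitrary and fixed here once.

The confidence level is 95% end to end — in the count limits and in the
envelope factor — and is not mixed per stage.

## The synthetic generator

`simulate_records()` emulates the statistical structure of automated-scanner
output so the pipeline is testable without image data. Per donor and dose it
draws `cells_per_dose` images, each clean, multi-cell or debris with fixed
probabilities, and flags each accepted with a class-dependent probability.

| parameter              | default            | meaning                                      |
|------------------------|--------------------|----------------------------------------------|
| `true_curve`           | (0.06, 0.07, 0.02) | ground-truth (C, α, β), dicentrics/cell      |
| `doses`                | 0, 0.5, 1, 2, 3, 4 | calibration doses (Gy)                       |
| `cells_per_dose`       | 1000               | images per donor per dose                    |
| `donors`               | S1, S2             | donor identifiers                            |
| `chrom_mean`, `chrom_sd` | 46, 9.75         | clean-image chromosome count (detector spread) |
| `frac_multicell`       | 0.05               | share of two-cell captures                   |
| `frac_debris`          | 0.08               | share of debris images                       |
| `false_dicentric_rate` | 2                  | spurious dicentrics per debris image         |
| `accept_model`         | 0.9 / 0.2 / 0.1    | P(accepted) for clean / multicell / debris   |

Design choices, and what they emulate:

* Clean chromosome counts are a rounded normal truncated at 1. A real
  detector miscounts: the spread (SD ≈ 9.75 around 46) is detector error,
  not biology. The defaults make the *unfiltered* count distribution span
  from near 0 to far above 100 with mean ≈ 45 and SD ≈ 18, while the
  accepted subset clusters near the mean — the qualitative signature of a
  scanner's raw versus accepted output.
* Multi-cell images are the sum of two independent clean cells (chromosomes
  and dicentrics alike), matching the reading that counts above ~100 mean
  two cells were captured.
* Debris images draw chromosomes uniformly on 0–10 and dicentrics
  Poisson(`false_dicentric_rate`) *independent of dose*, capped by the
  chromosome count. The rate of 2 reflects that a poor-quality image which
  fools the detector tends to produce a couple of false calls; it is the
  dose-independence, not the exact rate, that makes debris destroy the
  Poisson behaviour at high doses where the true yield differs most from
  the false-call rate.
* The accepted probabilities (0.9/0.2/0.1) encode a good but imperfect
  classifier: most clean images pass, some artifacts leak through — which is
  exactly why the IQR stage exists.
* All randomness flows from one integer seed; regeneration is bit-identical,
  making replicate studies enumerable.

What the generator does **not** model: the left skew of real detector counts
(real accepted data have median 46 but mean ≈ 41–42, because detectors miss
chromosomes more often than they invent them); donor-to-donor yield
differences; dose-dependent image quality (metaphase yield drops at high
dose); partial-body exposure or any non-Poisson truth in clean cells.
Passing tests therefore show the *pipeline logic* is correct under the
stated contamination model, not that any particular scanner's confusion
rates are reproduced.

## Numerical choices and degenerate inputs

* Quartiles: type 7; fences inclusive at the boundary.
* Identity-link Poisson fits start from a cell-weighted least-squares fit of
  the yields, with the intercept nudged positive so the initial mean is
  valid; non-convergence and non-positive fitted means are errors with the
  failing quantity named.
* Envelope intersections: bisection, tolerance 1e−6 Gy, bracket cap 20 Gy;
  non-intersection is decided by minimizing the envelope bound, never by
  bracket exhaustion alone.
* Curve archives serialize every number at 17 significant digits, so a
  write/read round trip is bit-exact.
* All-zero count vectors, totals of one dicentric, single-record groups and
  empty tables raise typed conditions (`dcadose_degenerate_data`,
  `dcadose_insufficient_data`, ...) rather than producing NaN.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run simulation studies at sizes
chosen to keep Monte-Carlo error well inside the asserted tolerances while
remaining quick on a single CPU: 10 000 cells for law-of-large-numbers
checks on the generator; 50 replicates of 5 000 cells/dose for
coefficient-recovery-at-printed-precision rates; 1 000 groups of 500 cells
for the u-test type-I error; 100 randomized curves against a 10 000-point
grid oracle for the envelope intersections; and 30 full pipeline replicates
(12 000 images each) for the overdispersion-and-repair study. The full suite
runs in well under a minute of simulation time per file.

## Known limitations

* Whole-body, acute, low-LET exposure only: no zero-inflated or mixed
  Poisson models for partial-body exposure, no dose-rate (G-function)
  corrections, no high-LET linear-only fits.
* The calibration design stops at 4 Gy; extrapolating estimates far above
  the calibrated range rests entirely on the quadratic term.
* The quasi-Poisson scale is estimated from very few dose points and is
  accordingly noisy; the floor at 1 protects against anti-conservatism but
  not against occasional over-inflation.
* Triage categories are attached to the point estimate only; a sample whose
  confidence interval straddles a category boundary should be triaged with
  the interval in view (`dose_lower_gy`, `dose_upper_gy` are always
  reported).
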