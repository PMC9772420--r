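Package: dcadose
Title: Dicentric Chromosome Assay Biodosimetry from Automated Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cytogenetic biodosimetry with automated dicentric
    chromosome scoring. Harmonizes per-image scoring records by quality flag
    and interquartile-range chromosome-count filtering, tests Poisson
    conformity of per-cell dicentric counts (dispersion index and Papworth
    u-test), fits linear-quadratic dose-response calibration curves by
    quasi-Poisson regression with a 95 percent confidence envelope, and
    estimates absorbed dose with confidence limits and triage categories
    from observed yields via Merkle's method. Includes a synthetic generator
    that emulates automated-scanner output, including multi-cell captures,
    debris images and false dicentric calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
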