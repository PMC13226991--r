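Package: platecal
Title: Plate-to-Plate Calibration Transfer for HPTLC Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative high-performance thin-layer chromatography
    (HPTLC) densitometry built around a single-point response-factor calibration
    transfer: per-plate second-order calibration curves, inverse prediction,
    LOD/LOQ estimation, a cross-plate mean calibration curve, and the per-plate
    "iterative factor" that rescales mean-curve quantifications from one
    reference standard. Includes ICH-style method-validation statistics
    (precision, robustness, recovery, spectral specificity), Bland-Altman
    equivalence analysis with a-priori margins, paired-comparison tests,
    root-sum-square measurement-uncertainty budgets, below-LOQ censoring with
    zero-imputed aggregation of dry-weight contents, and a seeded synthetic
    plate simulator with a mixed additive/multiplicative error structure for
    validating calibration-transfer claims against known truth.
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
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
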