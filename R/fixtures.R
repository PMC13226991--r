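#' Published koumine study tables as in-package fixtures
#'
#' Returns the published summary tables of the validated koumine HPTLC study
#' that this package's methods are benchmarked against, transcribed verbatim
#' at the printed precision. These are *inputs* for golden tests and for the
#' aggregation/sensitivity entry points — none of them is ever fitted to.
#'
#' @return A named list:
#' \describe{
#'   \item{table1}{Intra-day precision and inter-day reproducibility RSDs (%)
#'     per standard concentration (µg/mL).}
#'   \item{table2}{The 28 per-plate second-order calibration curves
#'     (`a2`, `a1`, `a0` with response in AU and concentration in µg/mL, plus
#'     printed R²).}
#'   \item{table3, table4, table5}{Robustness sweeps of Rf under changes of
#'     developing-solvent volume, equilibration time and dosage speed: the
#'     three measured Rf values per track plus printed mean and RSD.}
#'   \item{table6}{Per-sample mean koumine content (µg/mg dry weight), its
#'     `pm` (the printed "±" dispersion), replicate RSD (%), and the
#'     specificity correlation with the koumine reference spectrum. Censored
#'     rows (printed "--", below LOQ) carry `censored = TRUE` and `NA` values.}
#'   \item{table7}{Spike-recovery rows (original, added, detected in µg/mL,
#'     printed recovery % and RSD %). The stem row's printed recovery is
#'     inconsistent with detected/(original+added) and is flagged
#'     `erratum = TRUE`; the recomputed value is in `recovery_computed`.}
#'   \item{table8}{Reference-level sensitivity matrix: signed % difference
#'     between factor-transferred and plate-specific quantification for ten
#'     plates at five candidate reference levels (µg/mL).}
#'   \item{subgroups}{The editorially selected 33-sample province/part id
#'     lists used for the subgroup means.}
#'   \item{constants}{Printed scalar anchors: mean LOD and LOQ (µg/mL), the
#'     printed (non-reproducible, never used computationally) mean-curve
#'     equation, the equivalence statistics (variance of % differences, paired
#'     t, p, correlation, Bland–Altman limits of agreement), the iterative
#'     factor's relative uncertainty (3.77%), and the a-priori equivalence
#'     margins (±5% relative, ±0.15 µg/mg absolute).}
#' }
#'
#' @examples
#' fx <- published_fixtures()
#' fx$table6[fx$table6$sample_id == "GW001-S", ]
#' fx$subgroups$Fujian$root
#' @export
published_fixtures <- function() {
  table1 <- tibble::tribble(
    ~concentration, ~intra_day_rsd, ~inter_day_rsd,
    125, 3.6082, 3.8781,
    250, 3.7736, 2.7730,
    500, 2.9773, 2.5772,
    1000, 1.7697, 1.5906,
    2000, 1.2907, 1.9726
  )

  table2 <- tibble::tibble(
    plate = 1:28,
    a2 = c(
      -3, -3, -3, -3, -3, -3, -3, -3, -3, -4, -4, -4, -3, -3,
      -3, -3, -3, -3, -2, -3, -3, -3, -4, -4, -2, -3, -4, -4
    ) * 1e-9,
    a1 = c(
      2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2,
      2, 2, 2, 2, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2
    ) * 1e-5,
    a0 = c(
      5e-4, 3e-4, 2e-4, 8e-5, 2e-4, 2e-4, 3e-5, -4e-4, 4e-4, 4e-4,
      4e-4, 2e-4, -2e-5, 8e-5, -8e-4, 4e-4, 2e-4, 1.5e-3, 1.3e-3, 9e-4,
      3e-4, -1e-3, 4e-4, 7e-4, -4e-4, 3e-4, -3e-4, 9e-4
    ),
    r_squared = c(
      0.9999, 0.9999, 1, 0.9999, 0.9999, 1, 1, 0.9999, 0.9999, 1,
      0.9999, 0.9998, 0.9995, 0.9996, 0.9996, 0.9998, 0.9997, 0.9998,
      0.9997, 0.9998, 0.9998, 0.9997, 0.9997, 0.9999, 0.9999, 0.9998,
      0.9996, 1
    )
  )

  table3 <- tibble::tribble(
    ~track, ~rf_1, ~rf_2, ~rf_3, ~mean_printed, ~rsd_printed,
    "Koumine", 0.570, 0.580, 0.590, 0.580, 1.7241,
    "Stem", 0.570, 0.580, 0.580, 0.577, 1.0006,
    "Leaf", 0.580, 0.590, 0.590, 0.587, 0.9836
  )
  table3$condition_values <- list(c("5 mL", "10 mL", "15 mL"))[rep(1, 3)]

  table4 <- tibble::tribble(
    ~track, ~rf_1, ~rf_2, ~rf_3, ~mean_printed, ~rsd_printed,
    "Koumine", 0.550, 0.580, 0.590, 0.573, 3.6308,
    "Stem", 0.550, 0.580, 0.600, 0.577, 4.3641,
    "Leaf", 0.560, 0.580, 0.600, 0.580, 3.4483,
    "Root", 0.550, 0.580, 0.610, 0.580, 5.1724
  )
  table4$condition_values <- list(c("10 min", "20 min", "30 min"))[rep(1, 4)]

  table5 <- tibble::tribble(
    ~track, ~rf_1, ~rf_2, ~rf_3, ~mean_printed, ~rsd_printed,
    "Koumine", 0.58, 0.58, 0.57, 0.577, 1.0012,
    "Stem", 0.59, 0.58, 0.58, 0.583, 0.9897,
    "Leaf", 0.59, 0.58, 0.57, 0.580, 1.7241,
    "Root", 0.59, 0.57, 0.57, 0.577, 2.0024
  )
  table5$condition_values <- list(c("100 nL/s", "150 nL/s", "200 nL/s"))[rep(1, 4)]

  table6 <- tibble::tribble(
    ~sample_id, ~mean, ~pm, ~rsd, ~specificity_r,
    "GW001-S", 2.473, 0.097, 3.92, 0.9968,
    "GW002-S", 1.273, 0.071, 5.58, 0.9972,
    "GW003-S", 1.308, 0.068, 5.20, 0.996,
    "GW004-S", 1.155, 0.046, 3.98, 0.9902,
    "GW005-S", NA, NA, NA, NA,
    "GW006-S", 4.220, 0.216, 5.12, 0.9981,
    "GW007-S", 4.399, 0.179, 4.07, 0.9995,
    "GW008-S", 2.843, 0.122, 4.29, 0.999,
    "GW009-S", NA, NA, NA, NA,
    "GW010-S", 5.629, 0.218, 3.87, 0.9975,
    "GW011-S", 2.708, 0.106, 3.91, 0.9973,
    "GW012-S", 7.454, 0.218, 3.77, 0.9979,
    "GW013-S", 3.031, 0.118, 3.89, 0.9964,
    "GW014-S", 1.500, 0.057, 3.80, 0.9941,
    "GW015-S", 2.583, 0.099, 3.83, 0.9975,
    "GW016-S", 1.223, 0.063, 5.15, NA,
    "GW017-S", 4.000, 0.194, 4.85, 0.997,
    "GW018-S", 4.533, 0.191, 4.21, 0.997,
    "GW019-S", 4.376, 0.165, 3.77, 0.9982,
    "GW020-S", 4.920, 0.196, 3.98, 0.9973,
    "GW021-S", 4.234, 0.164, 3.87, 0.9966,
    "GW022-S", NA, NA, NA, NA,
    "GW023-S", 3.299, 0.172, 5.21, 0.9977,
    "GW024-S", 1.147, 0.044, 3.84, NA,
    "GW025-S", 1.637, 0.071, 4.34, 0.9947,
    "GW026-S", 2.349, 0.098, 4.17, 0.9913,
    "GW027-S", 1.466, 0.095, 6.48, 0.9985,
    "GW028-S", NA, NA, NA, NA,
    "GW029-S", NA, NA, NA, NA,
    "GW030-S", 1.645, 0.070, 4.26, 0.9916,
    "GW031-S", 1.130, 0.046, 4.07, 0.9976,
    "GW032-S", 1.518, 0.059, 3.82, 0.9903,
    "GW033-S", 1.879, 0.088, 4.58, 0.998,
    "GW034-S", 1.539, 0.066, 4.29, 0.9992,
    "GW035-S", 1.211, 0.079, 6.61, NA,
    "GW036-S", 2.008, 0.088, 4.33, 0.9989,
    "GW037-S", NA, NA, NA, NA,
    "GW038-S", 1.686, 0.116, 6.88, 0.9961,
    "GW039-R", 7.000, 0.370, 5.29, 0.9907,
    "GW040-R", 5.159, 0.212, 4.11, 0.993,
    "GW041-R", 9.000, 0.352, 3.80, 0.9989,
    "GW042-R", 3.717, 0.217, 5.87, 0.9972,
    "GW043-R", 6.067, 0.234, 3.79, 0.9965,
    "GW044-R", 1.322, 0.052, 3.86, 0.9982,
    "GW045-R", 6.356, 0.261, 4.06, 0.9977,
    "GW046-R", 7.561, 0.329, 4.32, 0.9957,
    "GW047-R", 3.294, 0.124, 3.76, 0.9972,
    "GW048-R", 7.418, 0.281, 3.77, 0.9977,
    "GW049-R", NA, NA, NA, NA,
    "GW050-R", 4.489, 0.174, 3.79, 0.9936,
    "GW051-R", 5.696, 0.222, 3.79, 0.9911,
    "GW052-L", NA, NA, NA, NA,
    "GW053-L", 3.036, 0.118, 3.79, 0.9905,
    "GW054-L", NA, NA, NA, NA,
    "GW055-L", NA, NA, NA, NA,
    "GW056-L", 1.945, 0.128, 6.58, NA,
    "GW057-L", NA, NA, NA, NA,
    "GW058-L", NA, NA, NA, NA,
    "GW059-L", 4.281, 0.181, 4.04, 0.9927,
    "GW060-L", 1.609, 0.074, 4.60, 0.9902,
    "GW061-L", NA, NA, NA, NA,
    "GW062-L", 1.032, 0.047, 4.55, NA,
    "GW063-L", 2.255, 0.108, 4.74, 0.9921,
    "GW064-L", NA, NA, NA, NA,
    "GW065-L", 1.578, 0.072, 4.56, 0.9907,
    "GW066-L", 3.044, 0.154, 5.03, 0.9903,
    "GW067-L", 1.592, 0.086, 5.34, 0.9918
  )
  table6$censored <- is.na(table6$mean)
  table6$part <- part_from_suffix(table6$sample_id)

  table7 <- tibble::tibble(
    sample = c("Stem", "Leaf", "Root"),
    original = c(247.30, 228.10, 498.80),
    added = c(250.00, 250.00, 500.00),
    detected = c(500.68, 456.49, 987.40),
    detected_pm = c(19.46, 18.31, 37.29),
    recovery_printed = c(109.49, 95.48, 98.86),
    rsd_printed = c(3.89, 4.01, 3.78)
  )
  table7$recovery_computed <-
    round(100 * table7$detected / (table7$original + table7$added), 2)
  # The stem row's printed recovery does not follow from its own
  # original/added/detected values under any standard recovery formula.
  table7$erratum <- abs(table7$recovery_printed - table7$recovery_computed) > 0.01

  table8_levels <- c(62.5, 125, 250, 500, 1000)
  table8_plates <- paste(
    "Plate", c(1, 10, 11, 12, 21, 23, 25, 26, 27, 28)
  )
  table8_values <- rbind(
    c(-31.75, 9.42, -3.74, 1.52, 2.41),
    c(-28.83, 7.39, -0.21, 2.95, 14.46),
    c(-39.84, 3.41, -3.69, 2.43, 13.07),
    c(75.34, 4.80, -0.09, 17.54, 5.72),
    c(42.06, 14.68, 1.36, -1.54, 9.94),
    c(-20.93, 2.39, 5.78, 4.64, 5.29),
    c(11.72, 5.36, 4.60, 6.74, 27.66),
    c(-25.30, -8.76, -0.07, -0.91, 6.69),
    c(-14.85, -13.19, 1.00, -1.04, 4.51),
    c(0.08, -10.69, 1.87, -0.51, 5.39)
  )
  table8 <- tibble::tibble(
    plate_id = rep(table8_plates, times = length(table8_levels)),
    level = rep(table8_levels, each = length(table8_plates)),
    pct_diff = as.vector(table8_values)
  )

  subgroups <- list(
    Fujian = list(
      stem = c(
        "GW037-S", "GW035-S", "GW023-S", "GW012-S", "GW033-S",
        "GW034-S", "GW027-S"
      ),
      root = c(
        "GW051-R", "GW050-R", "GW046-R", "GW041-R", "GW045-R",
        "GW043-R", "GW048-R"
      ),
      leaf = c(
        "GW052-L", "GW058-L", "GW059-L", "GW056-L", "GW066-L",
        "GW067-L", "GW061-L"
      )
    ),
    Guangxi = list(
      stem = c("GW032-S", "GW022-S", "GW029-S", "GW024-S"),
      root = c("GW049-R", "GW044-R", "GW042-R", "GW040-R"),
      leaf = c("GW062-L", "GW063-L", "GW053-L", "GW054-L")
    )
  )

  constants <- list(
    mean_lod = 30.6595, # µg/mL
    mean_loq = 92.9075, # µg/mL
    reference_level = 250, # µg/mL (0.25 mg/mL)
    # Printed mean-curve equation; numerically incompatible with the Table 2
    # coefficients under either unit reading, so it is carried verbatim as an
    # anchor and never used for computation.
    printed_mean_curve = list(
      a2 = 8.08e-4, a1 = 0.0406, a0 = -0.0188, r_squared = 0.998,
      usable = FALSE
    ),
    pct_diff_variance = 1.69, # %^2, printed "variance" of % differences
    paired_t = list(p_value = 0.506, t_value = 0.668, correlation = 0.987),
    loa = c(-0.07, 0.06), # µg/mg, printed 95% limits of agreement
    expanded_uncertainty_band = c(4.5, 8.8), # % relative, printed range
    u_factor_rel = 3.77, # % relative uncertainty of the factor
    margin_rel = 5, # % a-priori equivalence margin
    margin_abs = 0.15 # µg/mg absolute margin at the lower bound
  )

  list(
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    table5 = table5, table6 = table6, table7 = table7, table8 = table8,
    subgroups = subgroups, constants = constants
  )
}

#' Mean published calibration curve
#'
#' Coefficient-wise mean of the 28 published per-plate second-order calibration
#' curves (response AU vs concentration µg/mL). This is the package's default
#' "true" response curve for the plate simulator and the natural mean curve for
#' factor-transfer examples.
#'
#' @param conc_range Concentration validity range (µg/mL). The published
#'   curves were fitted on 125–2000 µg/mL; the default extends down to the
#'   62.5 µg/mL standard used in the transfer stage.
#' @return A [calibration_curve()].
#' @export
table2_mean_curve <- function(conc_range = c(62.5, 2000)) {
  t2 <- published_fixtures()$table2
  calibration_curve(
    a2 = mean(t2$a2), a1 = mean(t2$a1), a0 = mean(t2$a0),
    r_squared = mean(t2$r_squared),
    conc_range = conc_range, n_points = 5L
  )
}
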