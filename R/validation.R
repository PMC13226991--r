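#' Relative standard deviation
#'
#' `100 * sd / mean` with the sample (n − 1) standard deviation — the
#' convention that reproduces the published robustness tables.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(0.550, 0.580, 0.590)) # 3.6308
#' @export
rsd <- function(values) {
  check_number(values, "values")
  if (length(values) < 2) pc_abort("rsd needs at least 2 values")
  m <- mean(values)
  if (m == 0) pc_numeric_abort("rsd is undefined for zero mean")
  100 * sd(values) / m
}

#' Robustness summary of Rf values across method perturbations
#'
#' Summarises, per track, the retardation factors measured under deliberately
#' varied method conditions (developing-solvent volume, equilibration time,
#' dosage speed): mean, RSD, the max − min spread, and a pass flag at the
#' acceptance rule spread `< max_spread` (default 0.05 Rf units).
#'
#' @param rf_by_condition Data frame with columns `track`, `condition`, `rf`
#'   (one row per track x condition).
#' @param max_spread Acceptance threshold on the Rf spread (default 0.05).
#' @return Tibble with `track`, `n_conditions`, `mean_rf`, `rsd_percent`,
#'   `spread`, `pass`.
#' @details A track can show a small RSD yet fail the spread rule (or the
#'   reverse); both are reported so the discrepancy is visible rather than
#'   folded into one verdict.
#' @export
robustness_table <- function(rf_by_condition, max_spread = 0.05) {
  stopifnot(all(c("track", "condition", "rf") %in% names(rf_by_condition)))
  conditions <- unique(rf_by_condition$condition)
  per_track <- split(rf_by_condition$condition, rf_by_condition$track)
  bad <- names(per_track)[!vapply(
    per_track, function(x) setequal(x, conditions) && !anyDuplicated(x),
    logical(1)
  )]
  if (length(bad) > 0) {
    pc_schema_abort(sprintf(
      "track(s) %s do not cover the same condition set exactly once",
      paste(bad, collapse = ", ")
    ))
  }
  if (length(conditions) < 2) pc_abort("need at least 2 conditions per track")
  rf_by_condition |>
    dplyr::group_by(track = .data$track) |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      mean_rf = mean(.data$rf),
      rsd_percent = rsd(.data$rf),
      spread = max(.data$rf) - min(.data$rf),
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$spread < max_spread)
}

#' Spike-recovery accuracy
#'
#' `recovery% = 100 * detected / (original + added)` for a sample of known
#' endogenous content spiked with a known amount of standard.
#'
#' @param original Endogenous concentration (µg/mL), `>= 0`.
#' @param added Spiked concentration (µg/mL), `> 0`.
#' @param detected Measured concentration of the spiked sample (µg/mL), `>= 0`.
#' @param rsd_percent Optional replicate RSD to carry along.
#' @return Tibble with the inputs and `recovery_percent`.
#' @examples
#' recovery(228.10, 250.00, 456.49)$recovery_percent # 95.48
#' @export
recovery <- function(original, added, detected, rsd_percent = NA_real_) {
  check_number(original, "original", non_negative = TRUE)
  check_number(added, "added")
  if (any(added <= 0)) pc_abort("`added` must be > 0")
  check_number(detected, "detected", non_negative = TRUE)
  tibble::tibble(
    original = original, added = added, detected = detected,
    recovery_percent = 100 * detected / (original + added),
    rsd_percent = rsd_percent
  )
}

#' Spectral specificity correlation
#'
#' Pearson correlation of two in-situ UV absorbance spectra; the specificity
#' criterion for band identity is `r > 0.99`. Spectra on different wavelength
#' grids are linearly interpolated onto their overlap.
#'
#' @param a,b [uv_spectrum()] objects (or data frames with `wavelength`,
#'   `absorbance`).
#' @return Pearson correlation in \[-1, 1\].
#' @export
spectral_correlation <- function(a, b) {
  grab <- function(x) {
    if (!all(c("wavelength", "absorbance") %in% names(x))) {
      pc_schema_abort("spectra need `wavelength` and `absorbance` columns")
    }
    x
  }
  a <- grab(a)
  b <- grab(b)
  if (length(a$wavelength) == length(b$wavelength) &&
    all(a$wavelength == b$wavelength)) {
    ya <- a$absorbance
    yb <- b$absorbance
  } else {
    lo <- max(min(a$wavelength), min(b$wavelength))
    hi <- min(max(a$wavelength), max(b$wavelength))
    if (lo >= hi) pc_abort("spectra do not overlap in wavelength")
    grid <- a$wavelength[a$wavelength >= lo & a$wavelength <= hi]
    ya <- approx(a$wavelength, a$absorbance, xout = grid)$y
    yb <- approx(b$wavelength, b$absorbance, xout = grid)$y
  }
  if (sd(ya) == 0 || sd(yb) == 0) {
    pc_numeric_abort("zero-variance spectrum: correlation undefined")
  }
  cor(ya, yb)
}

#' Precision report across plates
#'
#' RSD per concentration level across repeated plates: the intra-day design
#' applies each calibration level once per plate on several plates the same
#' day; the inter-day design repeats this on separate days.
#'
#' @param data Data frame with columns `concentration`, `peak_area`, and a
#'   replication column named by `replicate_col` (e.g. `plate_id` or `day`).
#' @param design `"intra_day"` or `"inter_day"` (a label carried through).
#' @param replicate_col Column identifying the replicates (default
#'   `"plate_id"`).
#' @return Tibble of class `"precision_report"` with `concentration`, `n`,
#'   `rsd_percent`, `design`.
#' @export
precision_report <- function(data, design = c("intra_day", "inter_day"),
                             replicate_col = "plate_id") {
  design <- match.arg(design)
  stopifnot(all(c("concentration", "peak_area", replicate_col) %in% names(data)))
  out <- data |>
    dplyr::group_by(concentration = .data$concentration) |>
    dplyr::summarise(
      n = dplyr::n(),
      rsd_percent = rsd(.data$peak_area),
      .groups = "drop"
    ) |>
    dplyr::mutate(design = design)
  class(out) <- c("precision_report", class(out))
  out
}
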