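#' Root-sum-square combination of relative uncertainties
#'
#' Combines independent relative standard uncertainties (in percent) by the
#' root-sum-square rule for multiplicative models:
#' `sqrt(u1^2 + u2^2 + ...)`.
#'
#' @param components Numeric vector of relative uncertainties (%), all >= 0.
#' @return Combined relative uncertainty (%).
#' @examples
#' combine_rss(c(3, 4)) # 5
#' @export
combine_rss <- function(components) {
  check_number(components, "components", non_negative = TRUE)
  if (length(components) == 0) pc_abort("no uncertainty components supplied")
  sqrt(sum(components^2))
}

#' Per-sample measurement-uncertainty budget
#'
#' Builds the three-component budget behind a factor-transferred
#' quantification: the regression uncertainty of the mean calibration curve,
#' the repeatability of the sample's peak areas, and the relative uncertainty
#' of the iterative factor itself (default 3.77%, the conservative intra-day
#' precision of the calibration standards). Components combine root-sum-square
#' and are expanded by a coverage factor `k` (default 2, approximately 95%
#' coverage). The budget is flagged fit for purpose when the expanded relative
#' uncertainty does not exceed 10% — the acceptability bound for routine
#' quality control of botanical materials.
#'
#' @param u_cal_rel Relative calibration (regression) uncertainty (%).
#' @param u_rep_rel Relative repeatability of the sample peak area (%).
#' @param u_factor_rel Relative uncertainty of the iterative factor (%),
#'   default 3.77.
#' @param coverage_k Coverage factor, default 2.
#' @param fit_limit Fit-for-purpose bound on the expanded uncertainty (%),
#'   default 10.
#' @return One-row tibble of class `"uncertainty_budget"`: the components,
#'   `combined_rel`, `coverage_k`, `expanded_rel`, `fit_for_purpose`.
#' @examples
#' budget_for_sample(1.5, 1.0) # expanded ~8.36%, fit for purpose
#' @export
budget_for_sample <- function(u_cal_rel, u_rep_rel, u_factor_rel = 3.77,
                              coverage_k = 2, fit_limit = 10) {
  check_number(coverage_k, "coverage_k", positive = TRUE)
  combined <- combine_rss(c(u_cal_rel, u_rep_rel, u_factor_rel))
  expanded <- coverage_k * combined
  out <- tibble::tibble(
    u_cal_rel = u_cal_rel,
    u_rep_rel = u_rep_rel,
    u_factor_rel = u_factor_rel,
    combined_rel = combined,
    coverage_k = coverage_k,
    expanded_rel = expanded,
    fit_for_purpose = expanded <= fit_limit
  )
  class(out) <- c("uncertainty_budget", class(out))
  out
}

#' Relative calibration uncertainty at a concentration
#'
#' Linearized inverse-prediction uncertainty of a fitted calibration curve:
#' the standard error of the fitted response at `conc` (from the coefficient
#' covariance retained by [fit_second_order()] or [mean_curve()]) divided by
#' the local slope, expressed relative to `conc` in percent. This is the
#' curve-only component — replicate scatter of the unknown enters the budget
#' separately as `u_rep_rel`.
#'
#' @param curve A [calibration_curve()] carrying a coefficient covariance.
#' @param conc Concentration(s) in µg/mL, inside the curve's range.
#' @return Relative uncertainty(ies) in percent of `conc`.
#' @export
calibration_uncertainty <- function(curve, conc) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.null(curve$vcov)) {
    pc_abort("curve carries no coefficient covariance; fit it with fit_second_order()")
  }
  check_number(conc, "conc", positive = TRUE)
  rng <- curve$conc_range
  if (any(conc < rng[1] | conc > rng[2])) {
    pc_numeric_abort("concentration outside the calibration range")
  }
  vapply(conc, function(c0) {
    x <- c(1, c0, c0^2)
    v <- drop(t(x) %*% curve$vcov %*% x)
    u_conc <- sqrt(max(v, 0)) / abs(curve_fprime(curve, c0))
    100 * u_conc / c0
  }, numeric(1))
}
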