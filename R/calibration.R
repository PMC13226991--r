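#' Construct a second-order calibration curve object
#'
#' Represents the densitometric response model `area = a2*c^2 + a1*c + a0`
#' over a stated concentration validity range. Objects are normally produced
#' by [fit_second_order()] or [mean_curve()]; the constructor is exported for
#' building curves from published coefficients.
#'
#' @param a2,a1,a0 Polynomial coefficients (AU/(µg/mL)², AU/(µg/mL), AU).
#' @param r_squared Coefficient of determination of the fit (diagnostic).
#' @param conc_range Length-2 numeric, the concentration validity range
#'   (µg/mL), `min < max`.
#' @param n_points Number of calibration points behind the fit.
#' @param sigma Residual standard error of the fit (AU), if known.
#' @param vcov 3x3 covariance matrix of `(a0, a1, a2)`, if known; used by
#'   [calibration_uncertainty()].
#' @param df_residual Residual degrees of freedom.
#' @return An object of class `"calibration_curve"`.
#' @details The curve must be strictly monotone increasing over `conc_range`
#'   (the parabola vertex lies outside the range); otherwise inverse
#'   prediction would be ambiguous. A non-monotone curve is constructed with a
#'   warning and flagged `monotone = FALSE`, and [invert_curve()] refuses it.
#' @export
calibration_curve <- function(a2, a1, a0, r_squared = NA_real_,
                              conc_range, n_points = NA_integer_,
                              sigma = NA_real_, vcov = NULL,
                              df_residual = NA_real_) {
  check_number(c(a2, a1, a0), "coefficients")
  if (length(conc_range) != 2 || conc_range[1] >= conc_range[2]) {
    pc_abort("`conc_range` must be c(min, max) with min < max")
  }
  deriv_at <- function(c) a1 + 2 * a2 * c
  monotone <- deriv_at(conc_range[1]) > 0 && deriv_at(conc_range[2]) > 0
  if (!monotone) {
    rlang::warn(
      "calibration curve is not monotone increasing over its range; inverse prediction will refuse it",
      class = "platecal_nonmonotone"
    )
  }
  structure(
    list(
      a2 = a2, a1 = a1, a0 = a0, r_squared = r_squared,
      conc_range = as.numeric(conc_range), n_points = n_points,
      sigma = sigma, vcov = vcov, df_residual = df_residual,
      monotone = monotone
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> area = %.4g c^2 + %.4g c + %.4g\n", x$a2, x$a1, x$a0
  ))
  cat(sprintf(
    "  range: %.4g-%.4g ug/mL | n = %s | R^2 = %.6g | monotone: %s\n",
    x$conc_range[1], x$conc_range[2],
    ifelse(is.na(x$n_points), "?", x$n_points),
    x$r_squared, x$monotone
  ))
  invisible(x)
}

#' Fit a per-plate second-order calibration curve
#'
#' Ordinary least-squares quadratic fit of peak area on concentration, the
#' standard densitometric calibration model for wide HPTLC working ranges
#' where the response saturates at high load.
#'
#' @param standards Data frame of standard tracks with columns `concentration`
#'   (µg/mL) and `peak_area` (AU) — e.g. the standard rows of a
#'   [plate_table()]. At least 3 distinct concentrations are required.
#' @param weighting `"none"` (default, matching plain polynomial calibration)
#'   or `"inv_x2"` for 1/concentration² weights, an option for the
#'   heteroscedastic low end.
#' @return A [calibration_curve()] carrying `r_squared`, the residual standard
#'   error and the coefficient covariance for downstream uncertainty work.
#' @examples
#' std <- data.frame(concentration = c(125, 250, 500, 1000, 2000))
#' std$peak_area <- 2e-5 * std$concentration - 3e-9 * std$concentration^2 + 5e-4
#' fit_second_order(std)
#' @export
fit_second_order <- function(standards, weighting = c("none", "inv_x2")) {
  weighting <- match.arg(weighting)
  if (inherits(standards, "plate_table") && "kind" %in% names(standards)) {
    standards <- standards[standards$kind == "standard", ]
  }
  if (!all(c("concentration", "peak_area") %in% names(standards))) {
    pc_schema_abort("`standards` needs columns `concentration` and `peak_area`")
  }
  conc <- standards$concentration
  area <- standards$peak_area
  keep_rows <- is.finite(conc) & is.finite(area)
  conc <- conc[keep_rows]
  area <- area[keep_rows]
  if (length(unique(conc)) < 3) {
    pc_abort("at least 3 distinct concentrations are required for a quadratic fit")
  }
  w <- if (weighting == "inv_x2") 1 / conc^2 else NULL
  fit <- lm(area ~ conc + I(conc^2), weights = w)
  cf <- coef(fit)
  # exact synthetic standards are legitimate inputs; silence lm's
  # perfect-fit chatter but let anything else through
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  calibration_curve(
    a2 = unname(cf[3]), a1 = unname(cf[2]), a0 = unname(cf[1]),
    r_squared = sm$r.squared,
    conc_range = range(conc),
    n_points = length(conc),
    sigma = sm$sigma,
    vcov = sm$cov.unscaled * sm$sigma^2,
    df_residual = fit$df.residual
  )
}

# response and derivative, no range checks
curve_f <- function(curve, conc) curve$a2 * conc^2 + curve$a1 * conc + curve$a0
curve_fprime <- function(curve, conc) curve$a1 + 2 * curve$a2 * conc

range_with_tol <- function(curve, tol) {
  span <- diff(curve$conc_range)
  c(curve$conc_range[1] - tol * span, curve$conc_range[2] + tol * span)
}

#' Predict peak area from concentration
#'
#' @param curve A [calibration_curve()].
#' @param conc Concentration(s) in µg/mL.
#' @param extrapolation_tol Allowed extrapolation beyond the curve's
#'   concentration range, as a fraction of the range span (default 0: no
#'   extrapolation).
#' @return Predicted peak area(s) in AU.
#' @export
predict_area <- function(curve, conc, extrapolation_tol = 0) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_number(conc, "conc")
  rng <- range_with_tol(curve, extrapolation_tol)
  out_of_range <- conc < rng[1] | conc > rng[2]
  if (any(out_of_range)) {
    pc_numeric_abort(sprintf(
      "concentration %.6g ug/mL is outside the calibration range [%.6g, %.6g]",
      conc[which(out_of_range)[1]], curve$conc_range[1], curve$conc_range[2]
    ))
  }
  curve_f(curve, conc)
}

#' Invert a calibration curve (inverse prediction)
#'
#' Solves `a2*c^2 + a1*c + (a0 - area) = 0` for the concentration whose
#' predicted response equals the observed peak area, returning the unique root
#' inside the curve's validity range. Monotonicity over the range (enforced at
#' fit time) guarantees uniqueness. Falls back to the exact linear solution
#' when the quadratic coefficient is negligible at the range's scale.
#'
#' @inheritParams predict_area
#' @param area Observed peak area(s) in AU; must lie between the predicted
#'   areas at the range endpoints (extended by `extrapolation_tol`).
#' @return Concentration(s) in µg/mL.
#' @export
invert_curve <- function(curve, area, extrapolation_tol = 0) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_number(area, "area")
  if (!curve$monotone) {
    pc_numeric_abort(
      "curve is not monotone over its range: inverse prediction is ambiguous"
    )
  }
  rng <- range_with_tol(curve, extrapolation_tol)
  a_lo <- curve_f(curve, rng[1])
  a_hi <- curve_f(curve, rng[2])
  cmax <- max(abs(rng))
  linear <- abs(curve$a2) * cmax^2 < 1e-12 * max(abs(curve$a1) * cmax, .Machine$double.eps)

  solve_one <- function(y) {
    if (y < a_lo || y > a_hi) {
      pc_numeric_abort(sprintf(
        "area %.6g AU is outside the invertible response range [%.6g, %.6g]",
        y, a_lo, a_hi
      ))
    }
    if (linear || curve$a2 == 0) {
      return((y - curve$a0) / curve$a1)
    }
    disc <- curve$a1^2 - 4 * curve$a2 * (curve$a0 - y)
    if (disc < 0) {
      pc_numeric_abort(sprintf("no real root for area %.6g AU", y))
    }
    # numerically stable pair of roots
    q <- -(curve$a1 + sign(curve$a1) * sqrt(disc)) / 2
    roots <- c(q / curve$a2, (curve$a0 - y) / q)
    eps <- 1e-9 * diff(rng)
    inside <- roots >= rng[1] - eps & roots <= rng[2] + eps
    if (sum(inside) == 0) {
      pc_numeric_abort(sprintf(
        "no root inside the calibration range for area %.6g AU", y
      ))
    }
    if (sum(inside) == 2 && abs(diff(roots)) > eps) {
      pc_numeric_abort(sprintf(
        "both quadratic roots lie inside the calibration range for area %.6g AU; refusing to choose",
        y
      ))
    }
    roots[inside][1]
  }
  vapply(area, solve_one, numeric(1))
}

#' Limit of detection and quantification
#'
#' Implements the validation formulas `LOD = 3.3 * SE / S` and
#' `LOQ = 10 * SE / S`, where `SE` is a low-level standard error in response
#' units and `S` the slope of the linear range of the calibration curve. By
#' construction `LOQ/LOD = 10/3.3` exactly.
#'
#' @param se_low Standard error at low level (AU), `>= 0`.
#' @param slope Linear-range slope (AU per µg/mL), `> 0`.
#' @return A one-row tibble of class `"lod_loq"` with `se_low`, `slope`,
#'   `lod`, `loq` (µg/mL).
#' @export
lod_loq <- function(se_low, slope) {
  check_number(se_low, "se_low", non_negative = TRUE)
  check_number(slope, "slope")
  if (any(slope <= 0)) pc_abort("`slope` must be > 0")
  lod <- 3.3 * se_low / slope
  out <- tibble::tibble(
    se_low = se_low, slope = slope,
    lod = lod, loq = lod * (10 / 3.3)
  )
  class(out) <- c("lod_loq", class(out))
  out
}

#' Estimate LOD/LOQ from a plate's standards
#'
#' Operationalizes the "standard error of low-level concentration" as the
#' residual standard error of a straight-line fit over the `n_low` lowest
#' standard levels (in response units); the slope of that linear subrange is
#' `S`. This choice is isolated here so alternatives (e.g. the intercept
#' standard error) can be swapped in.
#'
#' @inheritParams fit_second_order
#' @param n_low Number of lowest levels defining the linear subrange
#'   (default 3).
#' @return A [lod_loq()] row.
#' @export
lod_loq_from_standards <- function(standards, n_low = 3) {
  if (inherits(standards, "plate_table") && "kind" %in% names(standards)) {
    standards <- standards[standards$kind == "standard", ]
  }
  levels_sorted <- sort(unique(standards$concentration))
  if (length(levels_sorted) < n_low) {
    pc_abort(sprintf("need at least %d distinct levels for the linear subrange", n_low))
  }
  low <- standards[standards$concentration %in% levels_sorted[seq_len(n_low)], ]
  fit <- lm(peak_area ~ concentration, data = low)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  lod_loq(se_low = sm$sigma, slope = unname(coef(fit)[2]))
}

#' Cross-plate mean calibration curve
#'
#' Coefficient-wise arithmetic mean of per-plate second-order fits — the one
#' curve that summarizes a plate series so later plates can be quantified
#' without a full standard series. The validity range is the intersection of
#' the member ranges; `r_squared` is recorded as the mean of the members'
#' values (a diagnostic, not a fit statistic). When members carry coefficient
#' covariances, the mean curve's covariance is `sum(vcov_i) / k^2`, i.e. the
#' covariance of the coefficient average.
#'
#' @param curves List of [calibration_curve()] objects (at least one).
#' @return A [calibration_curve()].
#' @export
mean_curve <- function(curves) {
  if (inherits(curves, "calibration_curve")) curves <- list(curves)
  if (length(curves) == 0) pc_abort("`curves` must contain at least one curve")
  stopifnot(all(vapply(curves, inherits, logical(1), "calibration_curve")))
  k <- length(curves)
  rng <- c(
    max(vapply(curves, function(x) x$conc_range[1], numeric(1))),
    min(vapply(curves, function(x) x$conc_range[2], numeric(1)))
  )
  if (rng[1] >= rng[2]) {
    pc_abort("curves have disjoint concentration ranges; no common validity range")
  }
  vcovs <- purrr::keep(purrr::map(curves, "vcov"), ~ !is.null(.x))
  vc <- if (length(vcovs) == k) Reduce(`+`, vcovs) / k^2 else NULL
  sigmas <- vapply(curves, function(x) x$sigma, numeric(1))
  calibration_curve(
    a2 = mean(vapply(curves, function(x) x$a2, numeric(1))),
    a1 = mean(vapply(curves, function(x) x$a1, numeric(1))),
    a0 = mean(vapply(curves, function(x) x$a0, numeric(1))),
    r_squared = mean(vapply(curves, function(x) x$r_squared, numeric(1))),
    conc_range = rng,
    n_points = sum(vapply(
      curves,
      function(x) ifelse(is.na(x$n_points), 0L, as.integer(x$n_points)),
      integer(1)
    )),
    sigma = if (all(is.finite(sigmas))) mean(sigmas) else NA_real_,
    vcov = vc,
    df_residual = NA_real_
  )
}

#' Mean LOD/LOQ across plates
#'
#' Arithmetic means of per-plate detection and quantification limits; the
#' standardized study-level limits. The exact `LOQ/LOD = 10/3.3` ratio is
#' preserved by linearity.
#'
#' @param per_plate A `"lod_loq"` tibble (one row per plate) or list of them.
#' @return A one-row tibble with `lod` and `loq` (µg/mL).
#' @export
mean_lod_loq <- function(per_plate) {
  if (is.list(per_plate) && !is.data.frame(per_plate)) {
    per_plate <- dplyr::bind_rows(per_plate)
  }
  if (nrow(per_plate) == 0) pc_abort("`per_plate` must be non-empty")
  tibble::tibble(lod = mean(per_plate$lod), loq = mean(per_plate$loq))
}
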