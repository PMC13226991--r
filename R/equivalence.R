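#' Paired comparison of two quantification methods
#'
#' Two-sided paired t-test on the per-sample differences, plus the Pearson
#' correlation of the paired values and the sample variance of the signed
#' percentage differences `100 * (x - y) / y` — the dispersion statistic used
#' to judge whether substituting the mean-curve method for plate-specific
#' calibration introduces unpredictable scatter (acceptance: variance < 2 %²).
#'
#' @param x,y Paired concentration (or content) vectors, equal length >= 3.
#' @return One-row tibble of class `"paired_quant_test"`: `t_value`,
#'   `p_value`, `df`, `correlation`, `pct_diff_variance`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(x, y) {
  check_number(x, "x")
  check_number(y, "y")
  if (length(x) != length(y)) pc_abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) pc_abort("paired test needs n >= 3")
  d <- x - y
  if (sd(d) == 0) {
    pc_numeric_abort(
      "differences have zero variance: the paired t statistic is degenerate"
    )
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  out <- tibble::tibble(
    t_value = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    correlation = cor(x, y),
    pct_diff_variance = var(100 * (x - y) / y),
    mean_diff = mean(d),
    n = n
  )
  class(out) <- c("paired_quant_test", class(out))
  out
}

#' Bland–Altman equivalence analysis
#'
#' Differences-versus-means method comparison with 95% limits of agreement
#' `mean_diff ± 1.96 * sd_diff` and an a-priori equivalence margin. The margin
#' is `max(margin_abs, margin_rel% of the grand mean)`; the two methods are
#' declared equivalent when both limits of agreement lie inside
#' `[-margin, +margin]`. The 1.96 multiplier is the conventional normal 95%
#' factor (no small-sample correction).
#'
#' @param x,y Paired values from the two methods, equal length >= 3 (e.g.
#'   dry-weight contents in µg/mg).
#' @param margin_rel Relative margin in percent (default 5, the a-priori
#'   alkaloid-quantification margin).
#' @param margin_abs Absolute margin in the measurement unit (default
#'   0.15 µg/mg, the absolute equivalent of ±5% near the quantification
#'   limit).
#' @return One-row tibble of class `"bland_altman"`: `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `margin`, `margin_rel`, `margin_abs`,
#'   `equivalent`. The per-pair (mean, difference) table is attached as
#'   attribute `"pairs"` for plotting.
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
#' ba$loa_low # -1.96
#' @export
bland_altman <- function(x, y, margin_rel = 5, margin_abs = 0.15) {
  check_number(x, "x")
  check_number(y, "y")
  if (length(x) != length(y)) pc_abort("`x` and `y` must have equal length")
  if (length(x) < 3) pc_abort("Bland-Altman analysis needs n >= 3")
  d <- x - y
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  loa <- mean_diff + c(-1.96, 1.96) * sd_diff
  margin <- max(margin_abs, margin_rel / 100 * abs(mean(m)))
  out <- tibble::tibble(
    n = length(x),
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    loa_low = loa[1],
    loa_high = loa[2],
    margin = margin,
    margin_rel = margin_rel,
    margin_abs = margin_abs,
    equivalent = loa[1] >= -margin && loa[2] <= margin
  )
  class(out) <- c("bland_altman", class(out))
  attr(out, "pairs") <- tibble::tibble(mean = m, diff = d)
  out
}

#' Ratio-plot error-structure diagnostic
#'
#' Compares each plate's standard responses to the cross-plate mean response
#' level by level. A purely multiplicative plate effect gives a constant ratio
#' per plate (zero slope against log-concentration); additive baseline error
#' inflates the ratio's dispersion at the low end and tilts the per-plate
#' ratio trend. The verdict is `"multiplicative-dominant"` when the mean
#' absolute per-plate slope over the upper half of the level grid is at or
#' below `slope_threshold` (per decade of concentration); the low-end
#' additive signature is reported separately as `low_end_additive`
#' (low-half ratio dispersion exceeding 1.5x the high-half dispersion).
#'
#' @param responses Data frame with `plate_id`, `concentration`, `peak_area`:
#'   the standard tracks of >= 2 plates on a shared level grid.
#' @param mean_response Optional data frame `concentration`, `mean_area`;
#'   defaults to the per-level mean across plates.
#' @param slope_threshold Absolute slope (ratio units per decade) below which
#'   the primary working range counts as multiplicative (default 0.05).
#' @return A list of class `"ratio_diagnostic"`: `ratios` (long tibble),
#'   `per_level` (level, ratio sd), `per_plate` (slopes overall and over the
#'   high half), `verdict`, `low_end_additive`.
#' @export
ratio_diagnostic <- function(responses, mean_response = NULL,
                             slope_threshold = 0.05) {
  stopifnot(all(c("plate_id", "concentration", "peak_area") %in% names(responses)))
  if (dplyr::n_distinct(responses$plate_id) < 2) {
    pc_abort("ratio diagnostic needs at least 2 plates")
  }
  if (is.null(mean_response)) {
    mean_response <- responses |>
      dplyr::group_by(concentration = .data$concentration) |>
      dplyr::summarise(mean_area = mean(.data$peak_area), .groups = "drop")
  }
  if (any(mean_response$mean_area == 0)) {
    pc_numeric_abort("zero mean response at a level: ratio undefined")
  }
  ratios <- responses |>
    dplyr::left_join(mean_response, by = "concentration") |>
    dplyr::mutate(ratio = .data$peak_area / .data$mean_area)
  if (any(is.na(ratios$mean_area))) {
    pc_schema_abort("plates and mean response must share the same level grid")
  }

  per_level <- ratios |>
    dplyr::group_by(concentration = .data$concentration) |>
    dplyr::summarise(
      ratio_sd = sd(.data$ratio),
      ratio_mean = mean(.data$ratio),
      .groups = "drop"
    )

  levels_sorted <- sort(unique(ratios$concentration))
  gm_mid <- sqrt(min(levels_sorted) * max(levels_sorted))
  high_levels <- levels_sorted[levels_sorted >= gm_mid]

  slope_of <- function(conc, ratio) {
    if (length(unique(conc)) < 2) {
      return(NA_real_)
    }
    unname(coef(lm(ratio ~ log10(conc)))[2])
  }
  per_plate <- ratios |>
    dplyr::group_by(plate_id = .data$plate_id) |>
    dplyr::summarise(
      slope = slope_of(.data$concentration, .data$ratio),
      slope_high = slope_of(
        .data$concentration[.data$concentration %in% high_levels],
        .data$ratio[.data$concentration %in% high_levels]
      ),
      .groups = "drop"
    )

  low_disp <- mean(per_level$ratio_sd[per_level$concentration < gm_mid])
  high_disp <- mean(per_level$ratio_sd[per_level$concentration >= gm_mid])
  mean_abs_high_slope <- mean(abs(per_plate$slope_high), na.rm = TRUE)

  structure(
    list(
      ratios = ratios,
      per_level = per_level,
      per_plate = per_plate,
      mean_abs_high_slope = mean_abs_high_slope,
      verdict = if (mean_abs_high_slope <= slope_threshold) {
        "multiplicative-dominant"
      } else {
        "mixed"
      },
      low_end_additive = isTRUE(low_disp > 1.5 * high_disp),
      slope_threshold = slope_threshold
    ),
    class = "ratio_diagnostic"
  )
}

#' @export
print.ratio_diagnostic <- function(x, ...) {
  cat("<ratio_diagnostic>\n")
  cat(sprintf(
    "  verdict: %s (mean |high-range slope| = %.4g, threshold %.3g)\n",
    x$verdict, x$mean_abs_high_slope, x$slope_threshold
  ))
  cat(sprintf("  low-end additive signature: %s\n", x$low_end_additive))
  invisible(x)
}
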