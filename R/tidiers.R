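# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a calibration curve
#'
#' @param x A [calibration_curve()].
#' @param ... Unused.
#' @return One row per coefficient (`term`, `estimate`, `std.error` when the
#'   fit covariance is available).
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 3)
  tibble::tibble(
    term = c("(Intercept)", "conc", "conc^2"),
    estimate = c(x$a0, x$a1, x$a2),
    std.error = unname(se)
  )
}

#' Glance at a calibration curve
#'
#' @inheritParams tidy.calibration_curve
#' @return One-row fit summary (`r.squared`, `sigma`, `n`, range, flags).
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$sigma,
    n = x$n_points,
    conc_min = x$conc_range[1],
    conc_max = x$conc_range[2],
    monotone = x$monotone
  )
}

#' Plot a calibration curve
#'
#' @param object A [calibration_curve()].
#' @param standards Optional data frame of `concentration`, `peak_area`
#'   points to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, standards = NULL, ...) {
  grid <- tibble::tibble(
    concentration = seq(object$conc_range[1], object$conc_range[2],
      length.out = 200
    )
  )
  grid$peak_area <- curve_f(object, grid$concentration)
  p <- ggplot2::ggplot(
    grid, ggplot2::aes(x = .data$concentration, y = .data$peak_area)
  ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(
      x = "concentration (µg/mL)", y = "peak area (AU)",
      title = "Second-order densitometric calibration"
    )
  if (!is.null(standards)) {
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(standards))
  }
  p
}

#' Tidy a sensitivity table
#'
#' @param x A `"sensitivity_table"` from [sensitivity_analysis()].
#' @param ... Unused.
#' @return The long plate x level percentage-difference tibble.
#' @method tidy sensitivity_table
#' @export
tidy.sensitivity_table <- function(x, ...) x$pct_diff

#' Glance at a sensitivity table
#'
#' @inheritParams tidy.sensitivity_table
#' @return One row: selected level and its column mean.
#' @method glance sensitivity_table
#' @export
glance.sensitivity_table <- function(x, ...) {
  sel <- x$column_means[x$column_means$level == x$selected_level, ]
  tibble::tibble(
    selected_level = x$selected_level,
    selected_mean_pct_diff = sel$mean_pct_diff,
    n_levels = nrow(x$column_means),
    n_flagged_cells = nrow(x$missing_cells)
  )
}

#' Plot a sensitivity table
#'
#' Per-plate signed percentage differences against candidate reference level,
#' with the column means highlighted.
#'
#' @param object A `"sensitivity_table"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensitivity_table
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  ggplot2::ggplot(
    object$pct_diff,
    ggplot2::aes(x = factor(.data$level), y = .data$pct_diff)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = object$column_means,
      ggplot2::aes(y = .data$mean_pct_diff),
      color = "firebrick", size = 3, shape = 18
    ) +
    ggplot2::labs(
      x = "candidate reference level (µg/mL)",
      y = "% difference vs plate-specific calibration",
      title = sprintf(
        "Reference-level sensitivity (selected: %g µg/mL)",
        object$selected_level
      )
    )
}

#' Plot a Bland–Altman analysis
#'
#' Differences against pair means with the bias line, 95% limits of agreement
#' and the a-priori equivalence margin.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_hline(
      yintercept = object$mean_diff, color = "steelblue"
    ) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = 2, color = "steelblue"
    ) +
    ggplot2::geom_hline(
      yintercept = c(-object$margin, object$margin),
      linetype = 3, color = "firebrick"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "pair mean", y = "difference (method 1 - method 2)",
      title = sprintf(
        "Bland-Altman: LoA [%.3g, %.3g], margin ±%.3g (%s)",
        object$loa_low, object$loa_high, object$margin,
        ifelse(object$equivalent, "equivalent", "not equivalent")
      )
    )
}

#' Plot a ratio diagnostic
#'
#' Observed/mean response ratios per plate against log concentration.
#'
#' @param object A [ratio_diagnostic()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_diagnostic
#' @export
autoplot.ratio_diagnostic <- function(object, ...) {
  ggplot2::ggplot(
    object$ratios,
    ggplot2::aes(
      x = .data$concentration, y = .data$ratio, group = .data$plate_id
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, color = "grey60") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (µg/mL, log scale)",
      y = "observed / mean response",
      title = sprintf("Ratio plot (%s)", object$verdict)
    )
}

#' Tidy a quantification study
#'
#' @param x A `"quant_study"` from [run_study()].
#' @param ... Unused.
#' @return The per-sample results tibble.
#' @method tidy quant_study
#' @export
tidy.quant_study <- function(x, ...) x$samples

#' Glance at a quantification study
#'
#' @inheritParams tidy.quant_study
#' @return One-row study summary.
#' @method glance quant_study
#' @export
glance.quant_study <- function(x, ...) {
  tibble::tibble(
    n_plates = nrow(x$curves),
    n_samples = nrow(x$samples),
    n_censored = sum(x$samples$censored),
    loq = x$limits$loq_used,
    mean_factor = mean(x$factors$factor),
    mean_expanded_rel = mean(x$samples$expanded_rel[!x$samples$censored]),
    reference_level = x$config$reference_level
  )
}

#' Plot study contents by group
#'
#' @param object A `"quant_study"`.
#' @param ... Unused.
#' @return A ggplot of per-sample dry-weight contents by part.
#' @method autoplot quant_study
#' @export
autoplot.quant_study <- function(object, ...) {
  df <- object$samples
  df$part <- part_from_suffix(df$sample_id)
  df$part[is.na(df$part)] <- "unknown"
  ggplot2::ggplot(
    df[!df$censored, ],
    ggplot2::aes(x = .data$part, y = .data$content)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = "koumine content (µg/mg dry weight)",
      title = "Per-sample contents (censored samples excluded)"
    )
}
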