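#' Per-plate iterative factor from one reference standard
#'
#' The iterative factor is the single-point calibration-transfer scalar of
#' this package: the ratio of the peak area that the cross-plate mean curve
#' predicts at a reference concentration to the peak area actually observed
#' for that standard on the plate at hand. Multiplying mean-curve
#' quantifications by this factor corrects the predominantly multiplicative
#' plate-to-plate response shift.
#'
#' @param mean_curve The cross-plate mean [calibration_curve()].
#' @param observed_ref_area Observed peak area (AU) of the reference standard
#'   on this plate; must be `> 0`.
#' @param reference_conc Reference concentration (µg/mL), inside the mean
#'   curve's range. The study default is 250 µg/mL (0.25 mg/mL).
#' @param iterate If `TRUE`, re-derives the factor from the corrected
#'   reference area until the update falls below `tol` (a fixed-point reading
#'   of "iterative"); for a single reference point this converges to the same
#'   ratio after one refinement, and the default `FALSE` computes the
#'   published single-pass ratio directly.
#' @param tol,max_iter Fixed-point controls used when `iterate = TRUE`.
#' @return A one-row tibble of class `"iterative_factor"` with
#'   `reference_conc`, `predicted_ref_area`, `observed_ref_area`, `factor`,
#'   `iterations`.
#' @examples
#' mc <- table2_mean_curve()
#' compute_factor(mc, observed_ref_area = 0.0048, reference_conc = 250)
#' @export
compute_factor <- function(mean_curve, observed_ref_area, reference_conc,
                           iterate = FALSE, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(mean_curve, "calibration_curve"))
  check_number(observed_ref_area, "observed_ref_area")
  if (observed_ref_area <= 0) {
    pc_numeric_abort("reference band not detected: observed reference area must be > 0")
  }
  predicted <- predict_area(mean_curve, reference_conc)
  fac <- predicted / observed_ref_area
  iterations <- 0L
  if (iterate) {
    repeat {
      iterations <- iterations + 1L
      corrected <- observed_ref_area * fac
      delta <- predicted / corrected
      fac <- fac * delta
      if (abs(delta - 1) < tol || iterations >= max_iter) break
    }
  }
  out <- tibble::tibble(
    reference_conc = reference_conc,
    predicted_ref_area = predicted,
    observed_ref_area = observed_ref_area,
    factor = fac,
    iterations = iterations
  )
  class(out) <- c("iterative_factor", class(out))
  out
}

as_factor_value <- function(factor) {
  if (inherits(factor, "iterative_factor") || is.data.frame(factor)) {
    factor <- factor$factor
  }
  check_number(factor, "factor", positive = TRUE)
  factor
}

#' Quantify a sample area through the mean curve and a plate factor
#'
#' Default (`mode = "concentration"`) follows the published order of
#' operations: invert the mean curve at the observed area, then multiply the
#' concentration by the plate factor. The alternative `mode = "response"`
#' rescales the observed area into the mean curve's response domain before
#' inversion; the two agree exactly for a linear response and differ by a
#' curvature term for a quadratic one.
#'
#' @param mean_curve The cross-plate mean [calibration_curve()].
#' @param factor An [compute_factor()] result or a bare positive number.
#' @param sample_area Observed sample peak area(s) in AU.
#' @param mode `"concentration"` (default) or `"response"`.
#' @param extrapolation_tol Passed to [invert_curve()].
#' @return Concentration(s) in µg/mL.
#' @export
quantify_iterative <- function(mean_curve, factor, sample_area,
                               mode = c("concentration", "response"),
                               extrapolation_tol = 0) {
  mode <- match.arg(mode)
  fac <- as_factor_value(factor)
  if (mode == "concentration") {
    invert_curve(mean_curve, sample_area, extrapolation_tol) * fac
  } else {
    invert_curve(mean_curve, sample_area * fac, extrapolation_tol)
  }
}

#' Signed percentage difference between two quantifications
#'
#' `100 * (x - y) / y`, the study's agreement statistic between a
#' factor-transferred concentration and the plate-specific one.
#'
#' @param c_iterative Concentration(s) from the mean curve + factor (µg/mL).
#' @param c_plate_specific Concentration(s) from the plate's own curve
#'   (µg/mL), non-zero.
#' @return Signed percentage difference(s).
#' @export
percent_difference <- function(c_iterative, c_plate_specific) {
  check_number(c_iterative, "c_iterative")
  check_number(c_plate_specific, "c_plate_specific")
  if (any(c_plate_specific == 0)) {
    pc_numeric_abort("plate-specific concentration must be non-zero")
  }
  100 * (c_iterative - c_plate_specific) / c_plate_specific
}

#' Reference-level sensitivity analysis
#'
#' For each plate and each candidate reference level, derives the iterative
#' factor from that level and quantifies the plate's check tracks both ways —
#' through the mean curve + factor and through the plate-specific curve — and
#' records the mean signed percentage difference. Column means over plates
#' rank the candidate levels; the selected level minimizes the absolute
#' column mean, with exact ties resolved toward the level closest to the
#' geometric mid-range (the best signal-to-noise compromise).
#'
#' @param plates A [plate_table()] tibble covering one or more plates; each
#'   plate must carry sample tracks (the check quantifications) and a standard
#'   at every candidate level.
#' @param mean_curve The cross-plate mean [calibration_curve()]; when `NULL`
#'   it is computed from per-plate fits of `plates`.
#' @param candidate_levels Candidate reference concentrations (µg/mL).
#' @param mode,extrapolation_tol Passed to [quantify_iterative()].
#' @return A `"sensitivity_table"` object: list with `pct_diff` (long tibble
#'   plate x level), `column_means`, `selected_level`, `candidate_levels`.
#'   Cells whose candidate level is missing on a plate are `NA`, excluded
#'   from the column mean, and listed in `missing_cells`.
#' @export
sensitivity_analysis <- function(plates, mean_curve = NULL,
                                 candidate_levels = c(62.5, 125, 250, 500, 1000),
                                 mode = "concentration",
                                 extrapolation_tol = 0.1) {
  plates <- plate_table(plates)
  plate_ids <- unique(plates$plate_id)
  fits <- purrr::map(
    purrr::set_names(plate_ids),
    ~ fit_second_order(plates[plates$plate_id == .x, ])
  )
  if (is.null(mean_curve)) mean_curve <- mean_curve(fits)

  cells <- purrr::map(plate_ids, function(pid) {
    pl <- plates[plates$plate_id == pid, ]
    std <- pl[pl$kind == "standard", ]
    smp <- pl[pl$kind == "sample", ]
    if (nrow(smp) == 0) {
      pc_abort(sprintf("plate %s has no sample tracks to use as checks", pid))
    }
    check_areas <- smp |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(area = mean(.data$peak_area), .groups = "drop") |>
      dplyr::pull("area")
    c_plate <- invert_curve(fits[[pid]], check_areas, extrapolation_tol)
    purrr::map(candidate_levels, function(lvl) {
      obs <- std$peak_area[abs(std$concentration - lvl) < 1e-9]
      if (length(obs) == 0) {
        return(tibble::tibble(plate_id = pid, level = lvl, pct_diff = NA_real_))
      }
      fac <- compute_factor(mean_curve, mean(obs), lvl)
      c_iter <- quantify_iterative(
        mean_curve, fac, check_areas,
        mode = mode, extrapolation_tol = extrapolation_tol
      )
      tibble::tibble(
        plate_id = pid, level = lvl,
        pct_diff = mean(percent_difference(c_iter, c_plate))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  missing_cells <- cells[is.na(cells$pct_diff), c("plate_id", "level")]
  sensitivity_summary(cells, candidate_levels = candidate_levels,
                      missing_cells = missing_cells)
}

#' Summarise a sensitivity matrix and select the reference level
#'
#' Computes the signed column means of a plate-by-level percentage-difference
#' table (the "Average" row) and selects the level with the smallest absolute
#' mean. Used both by [sensitivity_analysis()] and directly on published
#' sensitivity matrices.
#'
#' @param pct_diff Long tibble with columns `plate_id`, `level` (µg/mL) and
#'   `pct_diff` (%); `NA` cells are excluded from their column mean.
#' @param candidate_levels Level ordering (defaults to sorted unique levels).
#' @param missing_cells Optional tibble of flagged (plate, level) cells.
#' @return A `"sensitivity_table"` object (see [sensitivity_analysis()]).
#' @examples
#' fx <- published_fixtures()
#' st <- sensitivity_summary(fx$table8)
#' st$column_means
#' st$selected_level
#' @export
sensitivity_summary <- function(pct_diff, candidate_levels = NULL,
                                missing_cells = NULL) {
  stopifnot(all(c("plate_id", "level", "pct_diff") %in% names(pct_diff)))
  if (is.null(candidate_levels)) candidate_levels <- sort(unique(pct_diff$level))
  column_means <- pct_diff |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      mean_pct_diff = mean(.data$pct_diff, na.rm = TRUE),
      n_plates = sum(!is.na(.data$pct_diff)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$level, candidate_levels))
  best <- abs(column_means$mean_pct_diff)
  winners <- which(abs(best - min(best)) < 1e-12)
  if (length(winners) > 1) {
    gm_mid <- sqrt(min(candidate_levels) * max(candidate_levels))
    winners <- winners[which.min(abs(column_means$level[winners] - gm_mid))]
  }
  structure(
    list(
      pct_diff = tibble::as_tibble(pct_diff),
      column_means = column_means,
      selected_level = column_means$level[winners[1]],
      candidate_levels = candidate_levels,
      missing_cells = missing_cells %||%
        tibble::tibble(plate_id = character(), level = numeric())
    ),
    class = "sensitivity_table"
  )
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat("<sensitivity_table>\n")
  cat("column means (%):\n")
  print(as.data.frame(x$column_means), row.names = FALSE)
  cat(sprintf("selected reference level: %g ug/mL\n", x$selected_level))
  if (nrow(x$missing_cells) > 0) {
    cat(sprintf("%d flagged cell(s) excluded from means\n", nrow(x$missing_cells)))
  }
  invisible(x)
}
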