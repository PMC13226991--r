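#' Dry-weight content from solution concentration
#'
#' `content (µg/mg) = conc (µg/mL) * volume (mL) / mass (mg)`. With the
#' standard extraction of 100 mg dried powder in 1 mL solvent, a solution
#' concentration of 247.3 µg/mL corresponds to 2.473 µg/mg dry weight.
#'
#' @param conc Solution concentration(s), µg/mL.
#' @param mass_mg Dry mass extracted, mg (> 0). Default 100.
#' @param volume_mL Extraction volume, mL (> 0). Default 1.
#' @return Content in µg per mg dry weight.
#' @export
content_from_solution <- function(conc, mass_mg = 100, volume_mL = 1) {
  check_number(conc, "conc")
  check_number(mass_mg, "mass_mg", positive = TRUE)
  check_number(volume_mL, "volume_mL", positive = TRUE)
  conc * volume_mL / mass_mg
}

#' Censor concentrations below the limit of quantification
#'
#' Strict comparison: a value exactly at the LOQ is reportable.
#'
#' @param conc Concentration(s), µg/mL.
#' @param loq Limit of quantification, µg/mL (> 0).
#' @return Logical vector: `TRUE` where `conc < loq`.
#' @export
censor_below_loq <- function(conc, loq) {
  check_number(loq, "loq", positive = TRUE)
  check_number(conc, "conc")
  conc < loq
}

#' Aggregate per-sample contents with zero imputation of censored values
#'
#' Group means follow the study rule for below-LOQ results: censored samples
#' count zero in the numerator but remain in the denominator, so
#' `mean = sum(detected contents) / n_total`. The detected range
#' (`min_detected`, `max_detected`) is taken over uncensored samples only.
#'
#' @param results Data frame with `sample_id`, `content` (µg/mg; may be `NA`
#'   for censored rows), `censored` (logical). Extra columns are ignored.
#' @param metadata Optional [sample_metadata()] tibble supplying `part` and
#'   `province`; when absent, `part` is taken from the -S/-R/-L id suffix.
#' @param group_by Character vector of grouping keys among `"part"`,
#'   `"province"`; use `character()` for one overall group.
#' @param subset Optional character vector of sample ids to restrict to
#'   (every id must be present in `results`).
#' @return Tibble with the group keys plus `n_total`, `n_censored`,
#'   `mean_content`, `min_detected`, `max_detected`.
#' @examples
#' fx <- published_fixtures()
#' res <- dplyr::transmute(fx$table6,
#'   sample_id, content = mean, censored
#' )
#' aggregate_content(res, group_by = "part")
#' @export
aggregate_content <- function(results, metadata = NULL, group_by = "part",
                              subset = NULL) {
  stopifnot(all(c("sample_id", "content", "censored") %in% names(results)))
  res <- tibble::as_tibble(results)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, res$sample_id)
    if (length(unknown) > 0) {
      pc_abort(sprintf(
        "subset id(s) not present in results: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    res <- res[res$sample_id %in% subset, ]
  }
  if (!is.null(metadata)) {
    metadata <- sample_metadata(metadata)
    res <- dplyr::left_join(
      res, metadata[, intersect(names(metadata), c("sample_id", "part", "province"))],
      by = "sample_id"
    )
  }
  if ("part" %in% group_by && !"part" %in% names(res)) {
    res$part <- part_from_suffix(res$sample_id)
  }
  bad_keys <- setdiff(group_by, names(res))
  if (length(bad_keys) > 0) {
    pc_abort(sprintf(
      "grouping key(s) not available: %s", paste(bad_keys, collapse = ", ")
    ))
  }
  res$content_imputed <- ifelse(res$censored, 0, res$content)
  if (any(is.na(res$content_imputed))) {
    pc_abort("uncensored rows must carry a content value")
  }
  res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_censored = sum(.data$censored),
      mean_content = sum(.data$content_imputed) / dplyr::n(),
      min_detected = if (any(!.data$censored)) {
        min(.data$content[!.data$censored])
      } else {
        NA_real_
      },
      max_detected = if (any(!.data$censored)) {
        max(.data$content[!.data$censored])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Study-level run configuration
#'
#' Consolidates the tunable constants of the factor-transfer pipeline.
#'
#' @param reference_level Reference standard concentration for the factor
#'   (µg/mL), default 250.
#' @param correction_mode `"concentration"` (multiply the inverted
#'   concentration by the factor; the published order of operations) or
#'   `"response"` (rescale the area before inversion).
#' @param candidate_levels Candidate reference levels for sensitivity
#'   analysis (µg/mL).
#' @param margin_rel,margin_abs Bland–Altman equivalence margins (% and
#'   µg/mg).
#' @param coverage_k Coverage factor for expanded uncertainty.
#' @param u_factor_rel Relative uncertainty of the iterative factor (%).
#' @param extrapolation_tol Fractional range extension tolerated during
#'   inversion of noisy areas near the range edges.
#' @param loq Study LOQ in µg/mL, or `NULL` to estimate it from the plates
#'   (mean of per-plate values).
#' @param seed Optional integer seed recorded in run manifests.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(reference_level = 250,
                       correction_mode = c("concentration", "response"),
                       candidate_levels = c(62.5, 125, 250, 500, 1000),
                       margin_rel = 5, margin_abs = 0.15,
                       coverage_k = 2, u_factor_rel = 3.77,
                       extrapolation_tol = 0.1,
                       loq = NULL, seed = NULL) {
  correction_mode <- match.arg(correction_mode)
  check_number(reference_level, "reference_level", positive = TRUE)
  structure(
    list(
      reference_level = reference_level,
      correction_mode = correction_mode,
      candidate_levels = candidate_levels,
      margin_rel = margin_rel, margin_abs = margin_abs,
      coverage_k = coverage_k, u_factor_rel = u_factor_rel,
      extrapolation_tol = extrapolation_tol,
      loq = loq, seed = seed
    ),
    class = "run_config"
  )
}

#' End-to-end study quantification
#'
#' Composes the whole pipeline over a multi-plate study: per-plate
#' second-order fits, the cross-plate mean curve, per-plate LOD/LOQ and their
#' study means, the per-plate iterative factor at the reference level, and
#' per-sample quantification by both routes (mean curve + factor, and the
#' plate-specific curve), followed by LOQ censoring, dry-weight content
#' conversion, per-sample uncertainty budgets and part/province aggregation.
#'
#' @param plates A [plate_table()] tibble covering all plates; every plate
#'   needs a standard at the reference level.
#' @param metadata Optional [sample_metadata()] (mass/volume default to
#'   100 mg / 1 mL; part from the id suffix).
#' @param config A [run_config()].
#' @return A list of class `"quant_study"`:
#'   `samples` (per-sample tibble with `conc_iterative`, `conc_plate`,
#'   `content`, `censored`, replicate RSD, budget columns and provenance),
#'   `aggregates`, `curves` (per-plate coefficient tibble), `mean_curve`,
#'   `factors`, `limits` (study LOD/LOQ), `config`.
#' @export
run_study <- function(plates, metadata = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  plates <- plate_table(plates)
  plate_ids <- unique(plates$plate_id)

  fits <- purrr::map(
    purrr::set_names(plate_ids),
    ~ fit_second_order(plates[plates$plate_id == .x & plates$kind == "standard", ])
  )
  mc <- mean_curve(fits)
  limits_per_plate <- purrr::map(
    plate_ids,
    ~ lod_loq_from_standards(plates[plates$plate_id == .x, ])
  ) |> purrr::list_rbind()
  limits <- mean_lod_loq(limits_per_plate)
  loq <- config$loq %||% limits$loq

  factors <- purrr::map(plate_ids, function(pid) {
    std <- plates[plates$plate_id == pid & plates$kind == "standard", ]
    obs <- std$peak_area[abs(std$concentration - config$reference_level) < 1e-9]
    if (length(obs) == 0) {
      pc_abort(sprintf(
        "plate %s has no standard at the reference level %g ug/mL",
        pid, config$reference_level
      ))
    }
    dplyr::mutate(
      compute_factor(mc, mean(obs), config$reference_level),
      plate_id = pid, .before = 1
    )
  }) |> purrr::list_rbind()

  meta <- if (is.null(metadata)) NULL else sample_metadata(metadata)

  samples <- plates |>
    dplyr::filter(.data$kind == "sample") |>
    dplyr::group_by(plate_id = .data$plate_id, sample_id = .data$id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_area = mean(.data$peak_area),
      rsd_percent = ifelse(dplyr::n() >= 2, rsd(.data$peak_area), NA_real_),
      mean_rf = mean(.data$rf),
      .groups = "drop"
    )
  if (nrow(samples) == 0) pc_abort("study contains no sample tracks")

  quant_one <- function(pid, sid, area, rsd_rep) {
    fac <- factors$factor[factors$plate_id == pid]
    ci <- tryCatch(
      quantify_iterative(mc, fac, area,
        mode = config$correction_mode,
        extrapolation_tol = config$extrapolation_tol
      ),
      platecal_error = function(e) {
        pc_numeric_abort(sprintf(
          "sample %s on plate %s: %s", sid, pid, conditionMessage(e)
        ))
      }
    )
    cp <- tryCatch(
      invert_curve(fits[[pid]], area, config$extrapolation_tol),
      platecal_error = function(e) {
        pc_numeric_abort(sprintf(
          "sample %s on plate %s (plate-specific): %s", sid, pid,
          conditionMessage(e)
        ))
      }
    )
    tibble::tibble(conc_iterative = ci, conc_plate = cp)
  }
  quant <- purrr::pmap(
    list(samples$plate_id, samples$sample_id, samples$mean_area, samples$rsd_percent),
    function(pid, sid, area, r) quant_one(pid, sid, area, r)
  ) |> purrr::list_rbind()
  samples <- dplyr::bind_cols(samples, quant)

  mass <- rep(100, nrow(samples))
  volume <- rep(1, nrow(samples))
  if (!is.null(meta)) {
    ix <- match(samples$sample_id, meta$sample_id)
    mass <- ifelse(is.na(ix), 100, meta$mass_mg[ix])
    volume <- ifelse(is.na(ix), 1, meta$volume_mL[ix])
  }
  samples <- samples |>
    dplyr::mutate(
      censored = censor_below_loq(.data$conc_iterative, loq),
      content = ifelse(
        .data$censored, NA_real_,
        content_from_solution(.data$conc_iterative, mass, volume)
      ),
      content_plate = ifelse(
        .data$censored, NA_real_,
        content_from_solution(.data$conc_plate, mass, volume)
      ),
      pct_diff = percent_difference(.data$conc_iterative, .data$conc_plate)
    )

  u_cal <- calibration_uncertainty(
    mc, pmin(pmax(samples$conc_iterative, mc$conc_range[1]), mc$conc_range[2])
  )
  u_rep <- ifelse(is.na(samples$rsd_percent), 0, samples$rsd_percent)
  budgets <- purrr::map2(u_cal, u_rep, function(uc, ur) {
    budget_for_sample(uc, ur,
      u_factor_rel = config$u_factor_rel,
      coverage_k = config$coverage_k
    )
  }) |> purrr::list_rbind()
  samples <- dplyr::bind_cols(samples, budgets[, c(
    "u_cal_rel", "u_rep_rel", "u_factor_rel", "combined_rel", "expanded_rel",
    "fit_for_purpose"
  )])

  group_keys <- "part"
  if (!is.null(meta) && any(!is.na(meta$province))) {
    group_keys <- c("part", "province")
  }
  aggregates <- aggregate_content(
    samples[, c("sample_id", "content", "censored")],
    metadata = meta, group_by = group_keys
  )

  structure(
    list(
      samples = samples,
      aggregates = aggregates,
      curves = purrr::imap(fits, function(f, pid) {
        tibble::tibble(
          plate_id = pid, a2 = f$a2, a1 = f$a1, a0 = f$a0,
          r_squared = f$r_squared
        )
      }) |> purrr::list_rbind(),
      mean_curve = mc,
      factors = factors,
      limits = dplyr::mutate(limits, loq_used = loq),
      config = config
    ),
    class = "quant_study"
  )
}

#' @export
print.quant_study <- function(x, ...) {
  cat(sprintf(
    "<quant_study> %d plates, %d samples (%d censored at LOQ %.4g ug/mL)\n",
    nrow(x$curves), nrow(x$samples), sum(x$samples$censored),
    x$limits$loq_used
  ))
  cat(sprintf(
    "  mean curve: area = %.4g c^2 + %.4g c + %.4g | factor range %.3f-%.3f\n",
    x$mean_curve$a2, x$mean_curve$a1, x$mean_curve$a0,
    min(x$factors$factor), max(x$factors$factor)
  ))
  invisible(x)
}
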