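#' Configuration for the synthetic plate simulator
#'
#' The simulator emulates a multi-plate densitometric study with known truth:
#' every track's peak area is generated as
#' `area = g_plate * f(conc) * (1 + eps_prop) + eps_add`, with a shared
#' second-order true response `f`, a log-normal multiplicative plate effect
#' `g` (the between-plate response shift the iterative factor corrects),
#' track-level proportional measurement noise, and additive baseline noise
#' that dominates only at the low end of the level grid — the mixed error
#' structure seen in ratio plots of real plate series.
#'
#' @param true_curve The true concentration→area [calibration_curve()];
#'   defaults to [table2_mean_curve()], the mean of the 28 published curves.
#' @param levels Standard concentrations applied to every plate (µg/mL);
#'   default `c(62.5, 125, 250, 500, 1000)`, the transfer-stage series that
#'   includes the 250 µg/mL reference.
#' @param n_plates Number of plates (default 28, the published study size).
#' @param plate_effect_sd Log-sd of the multiplicative plate effect
#'   (default 0.02).
#' @param additive_sd Additive baseline noise sd in AU (default `5e-5`:
#'   ~3% of the lowest-level response, ~1% at the reference level, so the
#'   additive component dominates below the reference and the multiplicative
#'   one above it).
#' @param proportional_sd Relative measurement noise per track (default 0.02).
#' @param samples_per_plate Unknown samples per plate (default 9, the track
#'   budget left by the standards on a 20 x 10 cm plate).
#' @param sample_conc_range True sample concentration range (µg/mL), drawn
#'   uniformly; default `c(125, 900)`, matching dry-weight contents of about
#'   1.25–9 µg/mg at 100 mg / 1 mL.
#' @param replicates Replicate tracks per sample (default 3).
#' @param seed Integer seed; together with the per-plate substream derivation
#'   it fully determines the study.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(true_curve = table2_mean_curve(),
                       levels = c(62.5, 125, 250, 500, 1000),
                       n_plates = 28,
                       plate_effect_sd = 0.02,
                       additive_sd = 5e-5,
                       proportional_sd = 0.02,
                       samples_per_plate = 9,
                       sample_conc_range = c(125, 900),
                       replicates = 3,
                       seed = 1L) {
  stopifnot(inherits(true_curve, "calibration_curve"))
  check_number(levels, "levels", positive = TRUE)
  check_number(plate_effect_sd, "plate_effect_sd", non_negative = TRUE)
  check_number(additive_sd, "additive_sd", non_negative = TRUE)
  check_number(proportional_sd, "proportional_sd", non_negative = TRUE)
  if (n_plates < 1 || samples_per_plate < 0 || replicates < 1) {
    pc_abort("n_plates >= 1, samples_per_plate >= 0, replicates >= 1 required")
  }
  if (length(sample_conc_range) != 2 ||
    sample_conc_range[1] > sample_conc_range[2]) {
    pc_abort("`sample_conc_range` must be c(min, max)")
  }
  rng <- true_curve$conc_range
  if (any(levels < rng[1] | levels > rng[2]) ||
    sample_conc_range[1] < rng[1] || sample_conc_range[2] > rng[2]) {
    pc_abort("levels and sample concentrations must lie inside the true curve's range")
  }
  structure(
    list(
      true_curve = true_curve, levels = sort(levels), n_plates = n_plates,
      plate_effect_sd = plate_effect_sd, additive_sd = additive_sd,
      proportional_sd = proportional_sd,
      samples_per_plate = samples_per_plate,
      sample_conc_range = as.numeric(sample_conc_range),
      replicates = replicates, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a multi-plate densitometric study
#'
#' Generates plates of standard and sample tracks under a [sim_config()],
#' keeping the generating truth (per-sample true concentration, per-plate
#' effect `g`) alongside. Per-plate random substreams are derived
#' deterministically from the global seed, so increasing `n_plates` never
#' reshuffles earlier plates.
#'
#' @param config A [sim_config()].
#' @return A list of class `"simulated_study"`: `plates` (a [plate_table()]
#'   covering all plates), `truth` (tibble `plate_id`, `sample_id`,
#'   `true_conc`, `g`), `plate_effects`, `config`.
#' @examples
#' study <- simulate_study(sim_config(n_plates = 3, seed = 42))
#' dplyr::count(study$plates, kind)
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  f <- function(conc) curve_f(config$true_curve, conc)

  one_plate <- function(p) {
    pid <- sprintf("P%02d", p)
    set.seed(derive_seed(config$seed, p))
    g <- rlnorm(1, meanlog = 0, sdlog = config$plate_effect_sd)

    noisy_area <- function(conc) {
      n <- length(conc)
      pmax(
        g * f(conc) * (1 + rnorm(n, 0, config$proportional_sd)) +
          rnorm(n, 0, config$additive_sd),
        0
      )
    }

    standards <- tibble::tibble(
      plate_id = pid, kind = "standard",
      id = sprintf("L%g", config$levels),
      concentration = config$levels,
      peak_area = noisy_area(config$levels),
      rf = NA_real_, replicate = 1L
    )

    if (config$samples_per_plate > 0) {
      true_conc <- runif(
        config$samples_per_plate,
        config$sample_conc_range[1], config$sample_conc_range[2]
      )
      sid <- sprintf("%s-S%02d", pid, seq_len(config$samples_per_plate))
      smp <- tibble::tibble(
        plate_id = pid, kind = "sample",
        id = rep(sid, each = config$replicates),
        concentration = NA_real_,
        peak_area = noisy_area(rep(true_conc, each = config$replicates)),
        rf = pmin(pmax(rnorm(
          config$samples_per_plate * config$replicates, 0.58, 0.005
        ), 0), 1),
        replicate = rep(seq_len(config$replicates), config$samples_per_plate)
      )
      truth <- tibble::tibble(
        plate_id = pid, sample_id = sid, true_conc = true_conc, g = g
      )
    } else {
      smp <- NULL
      truth <- tibble::tibble(
        plate_id = character(), sample_id = character(),
        true_conc = numeric(), g = numeric()
      )
    }
    list(
      tracks = dplyr::bind_rows(standards, smp),
      truth = truth,
      g = tibble::tibble(plate_id = pid, g = g)
    )
  }

  parts <- purrr::map(seq_len(config$n_plates), one_plate)
  structure(
    list(
      plates = plate_table(purrr::list_rbind(purrr::map(parts, "tracks"))),
      truth = purrr::list_rbind(purrr::map(parts, "truth")),
      plate_effects = purrr::list_rbind(purrr::map(parts, "g")),
      config = config
    ),
    class = "simulated_study"
  )
}

#' Strategy comparison against simulated truth
#'
#' Quantifies every simulated sample three ways — plate-specific curve, bare
#' mean curve, and mean curve rescaled by the per-plate iterative factor —
#' and scores each strategy against the generating truth: mean signed bias
#' (%) and RMSE (%) overall and per concentration tercile.
#'
#' @param config A [sim_config()] (a study is generated internally), or a
#'   `"simulated_study"` to score an existing one.
#' @param reference_level Reference concentration for the factor (µg/mL).
#' @param mode Correction domain for [quantify_iterative()].
#' @param extrapolation_tol Inversion tolerance for noisy areas near range
#'   edges.
#' @return A list of class `"sim_recovery"`: `per_sample` (per-sample errors
#'   by strategy), `summary` (strategy x tercile bias/RMSE, tercile
#'   `"overall"` included).
#' @export
recovery_experiment <- function(config = sim_config(), reference_level = 250,
                                mode = "concentration",
                                extrapolation_tol = 0.1) {
  study <- if (inherits(config, "simulated_study")) config else simulate_study(config)
  plates <- study$plates
  plate_ids <- unique(plates$plate_id)

  fits <- purrr::map(
    purrr::set_names(plate_ids),
    ~ fit_second_order(plates[plates$plate_id == .x, ])
  )
  mc <- mean_curve(fits)

  factors <- purrr::map_dbl(purrr::set_names(plate_ids), function(pid) {
    std <- plates[plates$plate_id == pid & plates$kind == "standard", ]
    obs <- std$peak_area[abs(std$concentration - reference_level) < 1e-9]
    if (length(obs) == 0) {
      pc_abort(sprintf("plate %s lacks the reference level", pid))
    }
    compute_factor(mc, mean(obs), reference_level)$factor
  })

  areas <- plates |>
    dplyr::filter(.data$kind == "sample") |>
    dplyr::group_by(plate_id = .data$plate_id, sample_id = .data$id) |>
    dplyr::summarise(area = mean(.data$peak_area), .groups = "drop") |>
    dplyr::left_join(study$truth, by = c("plate_id", "sample_id"))

  per_sample <- areas |>
    dplyr::mutate(
      conc_plate = purrr::map2_dbl(
        .data$plate_id, .data$area,
        ~ invert_curve(fits[[.x]], .y, extrapolation_tol)
      ),
      conc_mean = invert_curve(mc, .data$area, extrapolation_tol),
      conc_factor = purrr::map2_dbl(
        .data$plate_id, .data$area,
        ~ quantify_iterative(mc, factors[[.x]], .y,
          mode = mode, extrapolation_tol = extrapolation_tol
        )
      ),
      tercile = cut(
        .data$true_conc,
        breaks = stats::quantile(.data$true_conc, probs = c(0, 1 / 3, 2 / 3, 1)),
        labels = c("low", "mid", "high"), include.lowest = TRUE
      )
    ) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("conc_plate", "conc_mean", "conc_factor")),
      names_to = "strategy", values_to = "conc", names_prefix = "conc_"
    ) |>
    dplyr::mutate(
      strategy = dplyr::recode(.data$strategy,
        plate = "plate_specific", mean = "mean_curve",
        factor = "mean_curve_factor"
      ),
      rel_err_pct = 100 * (.data$conc - .data$true_conc) / .data$true_conc
    )

  score <- function(df) {
    df |>
      dplyr::group_by(strategy = .data$strategy) |>
      dplyr::summarise(
        bias_pct = mean(.data$rel_err_pct),
        rmse_pct = sqrt(mean(.data$rel_err_pct^2)),
        n = dplyr::n(),
        .groups = "drop"
      )
  }
  summary_tbl <- dplyr::bind_rows(
    dplyr::mutate(score(per_sample), tercile = "overall", .before = 1),
    per_sample |>
      dplyr::group_by(tercile = as.character(.data$tercile)) |>
      dplyr::group_modify(~ score(.x)) |>
      dplyr::ungroup()
  )

  structure(
    list(per_sample = per_sample, summary = summary_tbl, study = study),
    class = "sim_recovery"
  )
}

#' @export
print.sim_recovery <- function(x, ...) {
  cat("<sim_recovery> strategy scores (overall):\n")
  print(
    as.data.frame(x$summary[x$summary$tercile == "overall", ]),
    row.names = FALSE
  )
  invisible(x)
}

#' Simulate in-situ UV spectra
#'
#' Gaussian absorption profiles on the 200–400 nm densitometer grid with
#' multiplicative point noise; used to exercise the spectral-specificity
#' check (koumine's absorption maximum sits at 220 nm).
#'
#' @param n Number of spectra.
#' @param peak_nm Peak wavelength, inside \[200, 400\] nm (default 220).
#' @param noise_rel Relative noise per point (default 0.02).
#' @param seed Integer seed.
#' @param width_nm Gaussian width (sd) in nm (default 18).
#' @return A list of `n` [uv_spectrum()] objects.
#' @export
simulate_spectra <- function(n, peak_nm = 220, noise_rel = 0.02, seed = 1L,
                             width_nm = 18) {
  if (peak_nm < 200 || peak_nm > 400) {
    pc_abort("`peak_nm` must lie within the 200-400 nm scan range")
  }
  check_number(noise_rel, "noise_rel", non_negative = TRUE)
  set.seed(derive_seed(seed, 0))
  grid <- seq(200, 400, by = 1)
  profile <- exp(-(grid - peak_nm)^2 / (2 * width_nm^2)) + 0.02
  purrr::map(seq_len(n), function(i) {
    uv_spectrum(
      grid,
      profile * (1 + rnorm(length(grid), 0, noise_rel))
    )
  })
}
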