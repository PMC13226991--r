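test_that("zero noise with unit plate effects reproduces the true curve exactly", {
  cfg <- sim_config(
    n_plates = 2, plate_effect_sd = 0, additive_sd = 0, proportional_sd = 0,
    seed = 1
  )
  study <- simulate_study(cfg)
  std <- study$plates[study$plates$kind == "standard", ]
  expect_equal(
    std$peak_area,
    predict_area(cfg$true_curve, std$concentration),
    tolerance = 1e-12
  )
  expect_equal(study$plate_effects$g, rep(1, 2))
})

test_that("the seed fully determines a study and plates use stable substreams", {
  a <- simulate_study(sim_config(n_plates = 3, seed = 42))
  b <- simulate_study(sim_config(n_plates = 3, seed = 42))
  expect_identical(a$plates, b$plates)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(sim_config(n_plates = 3, seed = 43))
  expect_false(isTRUE(all.equal(a$plates$peak_area, c$plates$peak_area)))

  # adding plates never reshuffles the earlier ones
  big <- simulate_study(sim_config(n_plates = 5, seed = 42))
  expect_equal(
    big$plates[big$plates$plate_id %in% c("P01", "P02", "P03"), ],
    a$plates,
    ignore_attr = TRUE
  )
})

test_that("plate effects sample at the configured log-scale spread", {
  study <- simulate_study(sim_config(n_plates = 28, seed = 1))
  s <- sd(log(study$plate_effects$g))
  se <- 0.02 / sqrt(2 * 27)
  expect_gt(s, 0.02 - 3 * se)
  expect_lt(s, 0.02 + 3 * se)
})

test_that("strategy scoring is exact in the noise-free limit", {
  cfg <- sim_config(
    n_plates = 3, plate_effect_sd = 0, additive_sd = 0, proportional_sd = 0,
    seed = 2
  )
  rx <- recovery_experiment(cfg)
  overall <- rx$summary[rx$summary$tercile == "overall", ]
  expect_true(all(abs(overall$bias_pct) < 1e-9))
  expect_true(all(overall$rmse_pct < 1e-9))
})

test_that("the factor cancels multiplicative effects exactly for linear response", {
  lin <- linear_curve()
  study <- exact_study(lin, gs = c(0.8, 1.25))
  rx <- recovery_experiment(study)
  overall <- rx$summary[rx$summary$tercile == "overall", ]
  expect_lt(abs(overall$bias_pct[overall$strategy == "mean_curve_factor"]), 1e-9)
  expect_lt(overall$rmse_pct[overall$strategy == "mean_curve_factor"], 1e-9)
  # without the factor, every plate keeps its g/mean(g) bias; the signed
  # biases cancel across plates but the error does not
  expect_gt(overall$rmse_pct[overall$strategy == "mean_curve"], 5)
  per_plate_bias <- rx$per_sample |>
    dplyr::filter(.data$strategy == "mean_curve") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(bias = mean(.data$rel_err_pct), .groups = "drop")
  expect_true(all(abs(per_plate_bias$bias) > 5))
})

test_that("ratio diagnostics recover the generator's error structure", {
  std_of <- function(study) {
    s <- study$plates[study$plates$kind == "standard", ]
    tibble::tibble(
      plate_id = s$plate_id, concentration = s$concentration,
      peak_area = s$peak_area
    )
  }
  # no additive noise: multiplicative-dominant for every seeded study
  for (s in 1:3) {
    study <- simulate_study(sim_config(seed = s, additive_sd = 0, n_plates = 10))
    rd <- ratio_diagnostic(std_of(study))
    expect_equal(rd$verdict, "multiplicative-dominant")
  }
  # raising the additive noise inflates low-level ratio dispersion
  low_disp <- function(add_sd, s) {
    study <- simulate_study(sim_config(
      seed = s, additive_sd = add_sd, n_plates = 14
    ))
    rd <- ratio_diagnostic(std_of(study))
    mean(rd$per_level$ratio_sd[rd$per_level$concentration <= 125])
  }
  for (s in 1:3) {
    expect_gt(low_disp(4e-4, s), low_disp(0, s))
  }
})

test_that("estimated factors track 1/g at the proportional-noise scale", {
  cfg <- sim_config(n_plates = 80, additive_sd = 0, seed = 6, samples_per_plate = 0)
  study <- simulate_study(cfg)
  std <- study$plates[study$plates$kind == "standard", ]
  fits <- purrr::map(
    purrr::set_names(unique(std$plate_id)),
    ~ fit_second_order(std[std$plate_id == .x, ])
  )
  mc <- mean_curve(fits)
  facs <- purrr::map_dbl(unique(std$plate_id), function(pid) {
    obs <- std$peak_area[std$plate_id == pid & std$concentration == 250]
    compute_factor(mc, obs, 250)$factor
  })
  # factor * g should scatter around 1 with roughly the proportional sd
  resid <- facs * study$plate_effects$g
  expect_lt(abs(mean(resid) - 1), 0.01)
  expect_gt(sd(resid), 0.7 * 0.02)
  expect_lt(sd(resid), 1.3 * 0.02)
})

test_that("spectra honour the scan range and noise settings", {
  sp0 <- simulate_spectra(3, noise_rel = 0)
  expect_equal(
    spectral_correlation(sp0[[1]], sp0[[2]]), 1,
    tolerance = 1e-12
  )
  expect_equal(sp0[[1]]$wavelength[1], 200)
  expect_equal(max(sp0[[1]]$wavelength), 400)
  expect_error(simulate_spectra(2, peak_nm = 500), "scan range")
})
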