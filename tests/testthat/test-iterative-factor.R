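test_that("the factor is the predicted/observed reference-area ratio", {
  lin <- linear_curve()
  pred <- predict_area(lin, 250)
  expect_equal(compute_factor(lin, pred, 250)$factor, 1)
  expect_equal(compute_factor(lin, pred / 1.2, 250)$factor, 1.2)
  expect_error(compute_factor(lin, 0, 250), "reference band not detected")
  expect_error(compute_factor(lin, -0.01, 250), "reference band not detected")
  expect_error(compute_factor(lin, 0.004, 5000), "outside the calibration range")

  # fixed-point refinement converges to the same single-pass ratio
  it <- compute_factor(lin, pred / 1.2, 250, iterate = TRUE)
  expect_equal(it$factor, 1.2, tolerance = 1e-9)
  expect_gte(it$iterations, 1)
})

test_that("the factor is invariant to common rescaling of both responses", {
  mc <- table2_mean_curve()
  obs <- 0.004
  f1 <- compute_factor(mc, obs, 250)$factor
  k <- 3.7
  mc_k <- calibration_curve(
    a2 = k * mc$a2, a1 = k * mc$a1, a0 = k * mc$a0,
    conc_range = mc$conc_range
  )
  f2 <- compute_factor(mc_k, k * obs, 250)$factor
  expect_equal(f2, f1)
})

test_that("linear response makes factor correction exact for any plate effect", {
  lin <- linear_curve()
  for (g in c(0.8, 0.95, 1.1, 1.25)) {
    fac <- compute_factor(lin, g * predict_area(lin, 250), 250)
    expect_equal(fac$factor, 1 / g, tolerance = 1e-12)
    conc <- c(100, 250, 500, 1500)
    areas <- g * predict_area(lin, conc)
    expect_equal(
      quantify_iterative(lin, fac, areas, mode = "concentration"),
      conc,
      tolerance = 1e-12
    )
    expect_equal(
      quantify_iterative(lin, fac, areas, mode = "response"),
      conc,
      tolerance = 1e-12
    )
  }
})

test_that("quadratic response: modes differ for large effects, both stay within 2% at mid-range for plate effects at the study scale", {
  mc <- table2_mean_curve()
  # strong effect: response-domain correction is exact, concentration-domain
  # carries a curvature bias, so the two modes must separate
  g <- 0.8
  fac <- compute_factor(mc, g * predict_area(mc, 250), 250)
  a_mid <- g * predict_area(mc, 500)
  c_conc <- quantify_iterative(mc, fac, a_mid, mode = "concentration")
  c_resp <- quantify_iterative(mc, fac, a_mid, mode = "response")
  expect_equal(c_resp, 500, tolerance = 1e-9)
  expect_gt(abs(c_conc - c_resp), 1)

  # at the simulator's plate-effect scale (a few percent) both modes recover
  # the truth within 2% at mid-range
  for (g in c(0.97, 1.0, 1.03)) {
    fac <- compute_factor(mc, g * predict_area(mc, 250), 250)
    a <- g * predict_area(mc, 500)
    for (mode in c("concentration", "response")) {
      expect_lt(
        abs(quantify_iterative(mc, fac, a, mode = mode) - 500) / 500, 0.02
      )
    }
  }
})

test_that("percentage differences are signed and vanish on identity", {
  expect_equal(percent_difference(102, 100), 2)
  expect_equal(percent_difference(98, 100), -2)
  x <- c(0.5, 3, 250, 1e4)
  expect_equal(percent_difference(x, x), rep(0, 4))
  expect_error(percent_difference(1, 0), "non-zero")
})

test_that("sensitivity analysis scores candidate levels and breaks ties toward mid-range", {
  # exact multiplicative plates on a linear response: every cell is zero and
  # the tie resolves to the level nearest the geometric mid-range (250)
  lin <- linear_curve()
  plates <- purrr::imap(c(0.9, 1.0, 1.1), function(g, i) {
    exact_plate(lin, plate_id = sprintf("P%d", i), g = g)
  }) |> purrr::list_rbind()
  st <- sensitivity_analysis(plates)
  expect_true(all(abs(st$pct_diff$pct_diff) < 1e-9))
  expect_equal(st$selected_level, 250)
  expect_equal(nrow(st$missing_cells), 0)

  # a missing candidate level is flagged and excluded from its column mean
  plates2 <- plates[!(plates$plate_id == "P2" &
    plates$kind == "standard" & plates$concentration == 125), ]
  st2 <- sensitivity_analysis(plates2)
  expect_equal(nrow(st2$missing_cells), 1)
  expect_equal(st2$missing_cells$level, 125)
  expect_equal(
    st2$column_means$n_plates[st2$column_means$level == 125], 2
  )
})

test_that("sensitivity summaries average signed columns and pick the minimum", {
  toy <- tibble::tibble(
    plate_id = rep(c("A", "B"), each = 3),
    level = rep(c(100, 250, 500), 2),
    pct_diff = c(-4, 1, 6, 2, -2, 8)
  )
  ss <- sensitivity_summary(toy)
  expect_equal(ss$column_means$mean_pct_diff, c(-1, -0.5, 7))
  expect_equal(ss$selected_level, 250)
})
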