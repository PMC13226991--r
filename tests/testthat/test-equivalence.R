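test_that("paired test matches the textbook statistic and handles degeneracy", {
  # symmetric differences around equal means
  y <- c(10, 20, 30)
  x <- y + c(-1, 0, 1)
  pt <- paired_t_test(x, y)
  expect_equal(pt$t_value, 0)
  expect_equal(pt$p_value, 1)
  expect_equal(pt$df, 2)

  expect_error(paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  expect_error(paired_t_test(1:2, 2:3), "n >= 3")

  set.seed(50)
  n <- 50
  yy <- runif(n, 100, 900)
  xx <- yy * (1 + rnorm(n, 0, 0.02))
  got <- paired_t_test(xx, yy)
  d <- xx - yy
  t_manual <- mean(d) / (sd(d) / sqrt(n))
  p_manual <- 2 * stats::pt(-abs(t_manual), n - 1)
  expect_equal(got$t_value, t_manual, tolerance = 1e-12)
  expect_equal(got$p_value, p_manual, tolerance = 1e-12)
  expect_equal(got$correlation, cor(xx, yy), tolerance = 1e-12)
  expect_equal(got$pct_diff_variance, var(100 * d / yy), tolerance = 1e-12)
})

test_that("limits of agreement and margins behave as defined", {
  x <- c(1, 2, 3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_true(ba0$equivalent)

  expect_error(bland_altman(c(1, 2), c(2, 1)), "n >= 3")

  y <- c(10, 20, 30)
  ba <- bland_altman(y + c(-1, 0, 1), y)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  # margin is the larger of the absolute floor and 5% of the grand mean
  expect_equal(ba$margin, max(0.15, 0.05 * 20))

  # antisymmetry: swapping the methods mirrors the analysis
  set.seed(8)
  a <- runif(10, 1, 5)
  b <- a + rnorm(10, 0.1, 0.2)
  ab <- bland_altman(a, b)
  ba2 <- bland_altman(b, a)
  expect_equal(ba2$mean_diff, -ab$mean_diff)
  expect_equal(ba2$loa_low, -ab$loa_high)
  expect_equal(ba2$loa_high, -ab$loa_low)
  expect_equal(ba2$equivalent, ab$equivalent)
})

test_that("ratio diagnostic separates multiplicative from additive error", {
  lin <- linear_curve()
  levels <- c(62.5, 125, 250, 500, 1000)
  f <- function(c) predict_area(lin, c)

  # identical plates: all ratios one, all slopes zero
  same <- tibble::tibble(
    plate_id = rep(c("A", "B"), each = 5),
    concentration = rep(levels, 2),
    peak_area = rep(f(levels), 2)
  )
  rd0 <- ratio_diagnostic(same)
  expect_true(all(abs(rd0$ratios$ratio - 1) < 1e-12))
  expect_true(all(abs(rd0$per_plate$slope) < 1e-12))
  expect_equal(rd0$verdict, "multiplicative-dominant")

  # a pure multiplicative plate keeps a flat ratio at its own level
  mult <- tibble::tibble(
    plate_id = rep(c("A", "B"), each = 5),
    concentration = rep(levels, 2),
    peak_area = c(0.8 * f(levels), f(levels))
  )
  rd1 <- ratio_diagnostic(
    mult,
    mean_response = tibble::tibble(concentration = levels, mean_area = f(levels))
  )
  ra <- rd1$ratios[rd1$ratios$plate_id == "A", ]
  expect_equal(ra$ratio, rep(0.8, 5), tolerance = 1e-12)
  expect_true(all(abs(rd1$per_plate$slope) < 1e-12))
  expect_equal(rd1$verdict, "multiplicative-dominant")

  # an additive offset on a linear response tilts the ratio downward in
  # concentration: ratio = g + eps / (b * c)
  eps <- 2e-4
  addv <- tibble::tibble(
    plate_id = rep(c("A", "B"), each = 5),
    concentration = rep(levels, 2),
    peak_area = c(0.9 * f(levels) + eps, f(levels))
  )
  rd2 <- ratio_diagnostic(
    addv,
    mean_response = tibble::tibble(concentration = levels, mean_area = f(levels))
  )
  ra2 <- rd2$ratios[rd2$ratios$plate_id == "A", ]
  expect_equal(ra2$ratio, 0.9 + eps / f(levels), tolerance = 1e-12)
  expect_true(all(diff(ra2$ratio[order(ra2$concentration)]) < 0))
  expect_lt(rd2$per_plate$slope[rd2$per_plate$plate_id == "A"], 0)

  expect_error(
    ratio_diagnostic(same, mean_response = tibble::tibble(
      concentration = levels, mean_area = c(0, f(levels[-1]))
    )),
    "zero mean response"
  )
})

test_that("no-bias simulated comparisons show no systematic method difference", {
  # error components are shared within a plate, so the paired test is run at
  # its unit of independence: per-plate mean quantifications. In the no-bias
  # scenario the two methods should rarely separate, and the sample-level
  # pairs should stay tightly correlated.
  stats <- purrr::map(1:10, function(s) {
    rx <- recovery_experiment(sim_config(seed = s))
    w <- tidyr::pivot_wider(
      rx$per_sample[, c("plate_id", "sample_id", "strategy", "conc")],
      names_from = "strategy", values_from = "conc"
    )
    by_plate <- w |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::summarise(
        c_factor = mean(.data$mean_curve_factor),
        c_plate = mean(.data$plate_specific),
        .groups = "drop"
      )
    dplyr::mutate(
      paired_t_test(by_plate$c_factor, by_plate$c_plate),
      correlation_samples = cor(w$mean_curve_factor, w$plate_specific)
    )
  }) |> purrr::list_rbind()
  expect_gte(sum(stats$p_value > 0.05), 7)
  expect_true(all(stats$correlation_samples > 0.98))
  # mean differences stay well inside the paired dispersion
  expect_lt(abs(mean(stats$mean_diff)), 10)
})
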