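plate1_curve <- function() {
  # first published plate: y = -3e-9 x^2 + 2e-5 x + 5e-4 on 125-2000 ug/mL
  calibration_curve(
    a2 = -3e-9, a1 = 2e-5, a0 = 5e-4,
    conc_range = c(125, 2000)
  )
}

test_that("quadratic fits recover exact generating coefficients", {
  x <- 1:5
  fit <- fit_second_order(data.frame(
    concentration = x, peak_area = 2 * x^2 + 3 * x + 1
  ))
  expect_equal(fit$a2, 2, tolerance = 1e-9)
  expect_equal(fit$a1, 3, tolerance = 1e-9)
  expect_equal(fit$a0, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # refit from areas generated by a published plate equation at the five
  # working-range levels recovers its coefficients to >= 6 significant digits
  levels <- c(125, 250, 500, 1000, 2000)
  pc <- plate1_curve()
  refit <- fit_second_order(data.frame(
    concentration = levels,
    peak_area = predict_area(pc, levels)
  ))
  expect_equal(refit$a2, -3e-9, tolerance = 1e-7)
  expect_equal(refit$a1, 2e-5, tolerance = 1e-7)
  expect_equal(refit$a0, 5e-4, tolerance = 1e-7)

  # collinear points leave the quadratic term at numerical zero
  lin <- suppressWarnings(fit_second_order(data.frame(
    concentration = c(100, 200, 300, 400),
    peak_area = 2e-5 * c(100, 200, 300, 400)
  )))
  expect_lt(abs(lin$a2) * 400^2, 1e-10)
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)

  expect_error(
    fit_second_order(data.frame(
      concentration = c(100, 100, 200), peak_area = c(1, 2, 3)
    )),
    "3 distinct"
  )
})

test_that("fitting is scale-equivariant in the response", {
  set.seed(4)
  conc <- c(125, 250, 500, 1000, 2000)
  area <- 2e-5 * conc - 3e-9 * conc^2 + 5e-4 + rnorm(5, 0, 1e-4)
  f1 <- fit_second_order(data.frame(concentration = conc, peak_area = area))
  f2 <- fit_second_order(data.frame(concentration = conc, peak_area = 7 * area))
  expect_equal(f2$a2, 7 * f1$a2)
  expect_equal(f2$a1, 7 * f1$a1)
  expect_equal(f2$a0, 7 * f1$a0)
  expect_equal(f2$r_squared, f1$r_squared)
})

test_that("forward prediction follows the polynomial and respects the range", {
  lin <- calibration_curve(a2 = 0, a1 = 2, a0 = 0, conc_range = c(1, 100))
  expect_equal(predict_area(lin, 5), 10)
  expect_equal(predict_area(plate1_curve(), 500), 0.00975)
  expect_error(predict_area(plate1_curve(), 5000), "outside the calibration range")
  # extrapolation tolerance opens the window deliberately
  expect_silent(predict_area(plate1_curve(), 2050, extrapolation_tol = 0.05))
})

test_that("inverse prediction returns the unique in-range root", {
  lin <- calibration_curve(a2 = 0, a1 = 2, a0 = 0, conc_range = c(1, 100))
  expect_equal(invert_curve(lin, 10), 5)
  expect_equal(invert_curve(plate1_curve(), 0.00975), 500, tolerance = 1e-9)
  expect_error(
    invert_curve(plate1_curve(), predict_area(plate1_curve(), 125) / 2),
    "outside the invertible response range"
  )
  # non-monotone curves are refused outright
  nm <- suppressWarnings(calibration_curve(
    a2 = -1, a1 = 10, a0 = 0, conc_range = c(1, 9)
  ))
  expect_false(nm$monotone)
  expect_error(invert_curve(nm, 20), "not monotone")
})

test_that("invert is the exact inverse of predict across monotone curves", {
  set.seed(7)
  for (i in 1:25) {
    a1 <- runif(1, 1e-5, 1e-4)
    rng <- c(runif(1, 20, 100), runif(1, 900, 2500))
    # keep the vertex beyond the upper range end so the curve stays monotone
    a2 <- -runif(1, 0, 0.9) * a1 / (2 * rng[2])
    crv <- calibration_curve(
      a2 = a2, a1 = a1, a0 = runif(1, -1e-3, 1e-3), conc_range = rng
    )
    conc <- seq(rng[1], rng[2], length.out = 11)
    back <- invert_curve(crv, predict_area(crv, conc))
    expect_equal(back, conc, tolerance = 1e-9)
  }
})

test_that("detection limits follow the 3.3/10 standard-error rule", {
  x <- lod_loq(1, 1)
  expect_equal(x$lod, 3.3)
  expect_equal(x$loq, 10)
  y <- lod_loq(0.01, 0.002)
  expect_equal(y$lod, 16.5)
  expect_equal(y$loq, 50)
  expect_error(lod_loq(1, 0), "slope")

  # the LOQ/LOD ratio is forced by construction and survives averaging
  set.seed(2)
  per_plate <- lod_loq(runif(6, 0.001, 0.01), runif(6, 1e-5, 1e-4))
  expect_equal(per_plate$loq / per_plate$lod, rep(10 / 3.3, 6))
  m <- mean_lod_loq(per_plate)
  expect_equal(m$loq / m$lod, 10 / 3.3)

  # means of per-plate limits: single entry is the identity, pairs average
  one <- lod_loq(30 / 3.3, 1)
  expect_equal(mean_lod_loq(one)$lod, 30)
  expect_equal(mean_lod_loq(one)$loq, 300 / 3.3)
  two <- lod_loq(c(10, 20) / 3.3 * 1, 1)
  m2 <- mean_lod_loq(two)
  expect_equal(m2$lod, 15)
  expect_equal(m2$loq, 150 / 3.3)
  expect_error(mean_lod_loq(one[0, ]), "non-empty")
})

test_that("LOD/LOQ from standards uses the low linear subrange", {
  # exactly linear low end -> zero residual -> zero limits
  std <- data.frame(
    concentration = c(62.5, 125, 250, 500, 1000),
    peak_area = 2e-5 * c(62.5, 125, 250, 500, 1000)
  )
  ll <- lod_loq_from_standards(std)
  expect_equal(ll$slope, 2e-5, tolerance = 1e-9)
  expect_equal(ll$lod, 0, tolerance = 1e-9)
})

test_that("mean curve averages coefficients over the common range", {
  c1 <- calibration_curve(a2 = 0, a1 = 1, a0 = 0, conc_range = c(1, 10))
  expect_equal(mean_curve(list(c1))$a1, 1)
  c2 <- calibration_curve(a2 = 0, a1 = 3, a0 = 2, conc_range = c(2, 12))
  m <- mean_curve(list(c1, c2))
  expect_equal(c(m$a2, m$a1, m$a0), c(0, 2, 1))
  expect_equal(m$conc_range, c(2, 10))

  t2 <- published_fixtures()$table2
  curves <- purrr::pmap(t2[, c("a2", "a1", "a0")], function(a2, a1, a0) {
    calibration_curve(a2 = a2, a1 = a1, a0 = a0, conc_range = c(125, 2000))
  })
  m28 <- mean_curve(curves)
  expect_equal(m28$a2, -89 / 28 * 1e-9, tolerance = 1e-12)

  c3 <- calibration_curve(a2 = 0, a1 = 1, a0 = 0, conc_range = c(20, 30))
  expect_error(mean_curve(list(c1, c3)), "disjoint")
  expect_error(mean_curve(list()), "at least one")
})
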