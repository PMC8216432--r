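# The deterministic two-threshold mean function, its sharp limit, slope,
# gradient and trajectory summaries.

test_that("parameter validation rejects degenerate inputs", {
  expect_error(acclim_params(1, 1, 1, 2, 1), "td1")
  expect_error(acclim_params(1, 1, 1, 1, 2, r1 = 0), "positive")
  expect_error(acclim_params(NA, 1, 1, 1, 2), "finite")
  expect_error(acclim_curve_sharp(list(y0 = 1, v1 = 1, v2 = 1, td1 = 3, td2 = 2), 0),
               "td1")
})

test_that("smooth curve matches anchor values in the sharp-parameter limit", {
  p <- tcore_p1(r1 = 1e-6, r2 = 1e-6)$params
  expect_equal(acclim_curve(p, 0), 39.3, tolerance = 1e-8)
  # plateau value y0 + v1*td1 + v2*(td2 - td1), hand-computed
  expect_equal(acclim_curve(p, 10), 38.5488, tolerance = 1e-6)
  # zero slopes collapse the curve to a constant y0 at any day and smoothness
  pz <- acclim_params(5.5, 0, 0, 2, 7, r1 = 0.3, r2 = 2)
  expect_equal(acclim_curve(pz, c(-1, 0, 3.7, 10)), rep(5.5, 4))
})

test_that("softplus evaluation is overflow-safe for sharp transitions", {
  p <- acclim_params(100, -50, 5, 1, 6, r1 = 1e-9, r2 = 1e-9)
  y <- acclim_curve(p, c(-1, 0, 5, 10, 1e4))
  expect_true(all(is.finite(y)))
  expect_equal(y[5], acclim_curve_sharp(p, 1e4))
})

test_that("sharp limit is the anchored piecewise line with a terminal plateau", {
  pa <- adfi_p1()$params
  expect_equal(acclim_curve_sharp(pa, 0), 179)
  pt <- tcore_p1()$params
  expect_equal(acclim_curve_sharp(pt, pt$td1), 39.3 + 0.48 * 1.46)
  # beyond td2 the value is frozen at the td2 value for any preset
  for (lab in acclim_presets()$label) {
    p <- acclim_preset(lab)$params
    expect_equal(acclim_curve_sharp(p, 1e6), acclim_curve_sharp(p, p$td2))
  }
})

test_that("slope reaches its three asymptotes between well-separated thresholds", {
  p <- tcore_p1(r1 = 1e-3, r2 = 1e-3)$params
  expect_equal(acclim_slope(p, -1), 0.48, tolerance = 1e-6)
  expect_equal(acclim_slope(p, 4), -0.30, tolerance = 1e-6)
  expect_equal(acclim_slope(p, p$td2 + 10), 0, tolerance = 1e-6)
})

test_that("slope equals a finite-difference derivative of the curve", {
  h <- 1e-6
  for (lab in c("Tcore/P1", "ADFI/P1", "ADFI/P3/TTH")) {
    p <- acclim_preset(lab)$params
    d <- seq(-1, 10, by = 0.5)
    fd <- (acclim_curve(p, d + h) - acclim_curve(p, d - h)) / (2 * h)
    expect_equal(acclim_slope(p, d), fd, tolerance = 1e-6)
  }
})

test_that("analytic gradient matches central finite differences", {
  days <- c(-1, 0, 1.46, 3, 6.3, 10)
  for (lab in c("Tcore/P1", "ADFI/P1", "Tcore/HHH/P3")) {
    p <- acclim_preset(lab)$params
    g <- acclim_gradient(p, days)
    fd <- fd_gradient(p, days)
    expect_equal(unname(g), unname(fd), tolerance = 1e-6)
  }
  # y0 partial is exactly 1; equal slopes kill the td1 sensitivity of the kink
  p <- acclim_params(10, 2, 2, 1, 6)
  expect_equal(unname(acclim_gradient(p, seq(-1, 10))[, "y0"]), rep(1, 12))
  expect_equal(unname(acclim_gradient(p, 3)[, "td1"]), 0)
})

test_that("smooth curve converges to the sharp limit as r -> 0", {
  d <- seq(-1, 10, by = 0.01)
  tab <- acclim_presets()
  for (lab in tab$label) {
    p <- acclim_preset(lab)$params
    sharp <- acclim_curve_sharp(p, d)
    # proven envelope: the knot error of each softplus term is r*log(2)*|coef|
    for (r in c(1e-3, 1e-4)) {
      pr <- acclim_preset(lab, r1 = r, r2 = r)$params
      sup <- max(abs(acclim_curve(pr, d) - sharp))
      expect_lt(sup, 1.05 * r * log(2) * (abs(p$v1 - p$v2) + abs(p$v2)))
    }
  }
  # on the temperature scale the sup error at r = 1e-4 is below 1e-3
  for (lab in tab$label[tab$variable == "Tcore"]) {
    pr <- acclim_preset(lab, r1 = 1e-4, r2 = 1e-4)$params
    sup <- max(abs(acclim_curve(pr, d) - acclim_curve_sharp(pr, d)))
    expect_lt(sup, 1e-3)
  }
})

test_that("setting v2 = 0 removes all dependence on td2", {
  d <- seq(-1, 10, by = 0.25)
  p5 <- acclim_params(170, -30, 0, 1, 5)
  p9 <- acclim_params(170, -30, 0, 1, 9)
  expect_equal(acclim_curve(p5, d), acclim_curve(p9, d))
})

test_that("adding a constant to y0 translates the whole curve", {
  d <- seq(-1, 10, by = 0.37)
  p <- tcore_p1()$params
  pc <- p; pc$y0 <- p$y0 + 2.5
  expect_equal(acclim_curve(pc, d), acclim_curve(p, d) + 2.5)
})

test_that("trajectory summaries identify extrema and contrasts on the sharp limit", {
  s <- acclim_summaries(tcore_p1()$params, window = c(-1, 10))
  expect_true(s$defined)
  expect_equal(s$extremum_type, "peak")
  expect_equal(s$extremum_value, 39.3 + 0.48 * 1.46)
  expect_equal(s$min_day, 6.30)

  sa <- acclim_summaries(adfi_p1()$params, window = c(-1, 10))
  expect_equal(sa$extremum_type, "trough")
  expect_equal(sa$min_day, 0.01)
  # hand-derived: (179 - 39.1*0.01 + 5.34*7.96) - (179 + 39.1)
  expect_equal(sa$contrast, 3.0154, tolerance = 1e-10)

  sz <- acclim_summaries(acclim_params(7, 0, 0, 2, 6), window = c(-1, 10))
  expect_equal(sz$extremum_value, 7)
  expect_equal(sz$min_day, -1)  # flat curve: earliest day of the window

  # window excluding a threshold -> summaries flagged undefined
  su <- acclim_summaries(tcore_p1()$params, window = c(-1, 5))
  expect_false(su$defined)
  expect_true(is.na(su$min_day))
})
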