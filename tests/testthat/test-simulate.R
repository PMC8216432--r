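# Presets, trajectory cohort generator, and the full study generator.

test_that("built-in presets round-trip the published parameter values", {
  p <- acclim_preset("ADFI/P1")
  expect_identical(unname(unlist(p$params[c("y0", "v1", "v2", "td1", "td2")])),
                   c(179, -39.1, 5.34, 0.01, 7.97))
  expect_identical(c(p$sigma_r2, p$sigma_e2), c(300, 331))
  expect_equal(p$n_animals, 18)

  q <- acclim_preset("Tcore/P1")
  expect_identical(unname(unlist(q$params[c("y0", "v1", "v2", "td1", "td2")])),
                   c(39.3, 0.48, -0.30, 1.46, 6.30))
  expect_identical(c(q$sigma_r2, q$sigma_e2), c(0.038, 0.036))

  expect_identical(acclim_preset("Tcore/HHH/P3")$params$y0, 38.9)
  expect_identical(nrow(acclim_presets()), 16L)
  expect_false(anyDuplicated(acclim_presets()$label) > 0)
  expect_error(acclim_preset("Tcore/P9"), "unknown preset")
})

test_that("trajectory simulation is shaped and seeded correctly", {
  p <- adfi_p1()
  d <- simulate_trajectories(p, n_animals = 18, seed = 4)
  expect_s3_class(d, "trajectory_data")
  expect_equal(nrow(d), 18 * 12)
  expect_equal(sort(unique(d$day)), -1:10)
  d2 <- simulate_trajectories(p, n_animals = 18, seed = 4)
  expect_identical(d, d2)
  d3 <- simulate_trajectories(p, n_animals = 18, seed = 5)
  expect_false(identical(d$value, d3$value))
  expect_error(simulate_trajectories(p, n_animals = 5), "seed")
})

test_that("animal-mean dispersion matches the law of total variance", {
  p <- adfi_p1()  # sigma_r2 = 300, sigma_e2 = 331, 12 days
  d <- simulate_trajectories(p, n_animals = 2000, seed = 77)
  dev <- d$value - acclim_curve(p$params, d$day)
  v <- var(tapply(dev, d$animal_id, mean))
  expected <- 300 + 331 / 12
  expect_lt(abs(v - expected) / expected, 0.05)
})

test_that("within-animal residual variance converges to the preset value", {
  p <- tcore_p1()
  d <- simulate_trajectories(p, n_animals = 500, seed = 31)
  dev <- d$value - acclim_curve(p$params, d$day)
  within <- mean(tapply(dev, d$animal_id, var))
  expect_lt(abs(within - p$sigma_e2) / p$sigma_e2, 0.1)
})

test_that("study design matches the room-assignment table", {
  des <- study_design()
  expect_identical(des$groups, c("TTT", "HTT", "THT", "TTH", "HHH"))
  expect_identical(unname(des$rooms["HTT", ]), c("H", "T", "T"))
  expect_identical(unname(des$rooms["THT", ]), c("T", "H", "T"))
  expect_identical(unname(des$rooms["TTH", ]), c("T", "T", "H"))
  expect_identical(unname(des$rooms["HHH", ]), c("H", "H", "H"))
  expect_identical(unname(des$rooms["TTT", ]), c("T", "T", "T"))
})

test_that("simulated study has the full design and is reproducible", {
  st <- simulate_study(seed = 9)
  expect_equal(length(unique(st$animal_id)), 45)
  expect_true(all(table(unique(st[, c("animal_id", "group")])$group) == 9))
  expect_identical(sort(unique(st$period)), c("P1", "P2", "P3"))
  expect_identical(sort(unique(st$variable)),
                   c("ADFI_g_d", "BW_kg", "Tcore_C"))
  st2 <- simulate_study(seed = 9)
  expect_identical(st, st2)
  expect_false(identical(st$value, simulate_study(seed = 10)$value))
})

test_that("thermoneutral animals carry no challenge response", {
  st <- simulate_study(seed = 9)
  tt <- st[st$group == "TTT" & st$variable == "Tcore_C", ]
  # daily group means stay near the thermoneutral baseline in every period:
  # no challenge-shaped excursion during days 0..4
  for (pd in c("P1", "P2", "P3")) {
    sub <- tt[tt$period == pd, ]
    pre <- mean(sub$value[sub$day < 0])
    dur <- mean(sub$value[sub$day >= 0 & sub$day < 5])
    expect_lt(abs(dur - pre), 0.15)
  }
})

test_that("repeated challenges attenuate the simulated temperature peak", {
  # HHH peak (value at td1) declines from P1 to P3 by preset construction
  p1 <- acclim_preset("Tcore/HHH/P1")$params
  p3 <- acclim_preset("Tcore/HHH/P3")$params
  expect_gt(acclim_curve_sharp(p1, p1$td1), acclim_curve_sharp(p3, p3$td1))
  st <- simulate_study(seed = 9)
  hh <- st[st$group == "HHH" & st$variable == "Tcore_C", ]
  peak <- function(pd) {
    sub <- hh[hh$period == pd, ]
    max(tapply(sub$value[sub$day %in% 0:4], sub$day[sub$day %in% 0:4], mean))
  }
  expect_gt(peak("P1"), peak("P3"))
})

test_that("simulated body weight grows at the configured rate", {
  st <- simulate_study(seed = 9, bw_noise_sd = 0)
  bw <- st[st$variable == "BW_kg", ]
  a <- bw[bw$animal_id == bw$animal_id[1], ]
  gain <- (a$value[a$period == "P3" & a$day == 12] -
           a$value[a$period == "P1" & a$day == -3]) / 45
  expect_equal(gain, 1.2, tolerance = 1e-8)
})
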