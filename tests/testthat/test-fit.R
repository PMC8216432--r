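# Initialiser, NLMM fitter, adjusted R-squared, predictions and contrasts.

test_that("lattice initialiser recovers thresholds from noiseless sharp data", {
  p <- acclim_params(100, -20, 4, 1.5, 6.25)
  days <- -1:10
  recs <- data.frame(animal_id = rep(sprintf("a%d", 1:4), each = length(days)),
                     day = rep(days, 4),
                     value = rep(acclim_curve_sharp(p, days), 4))
  d <- trajectory_data(recs, variable = "Tcore")
  ini <- init_acclim(d, acclim_control())
  expect_lte(abs(ini$td1 - 1.5), 0.25)
  expect_lte(abs(ini$td2 - 6.25), 0.25)
  expect_equal(ini$y0, 100, tolerance = 1e-6)
})

test_that("lattice initialiser handles constant data and rejects tiny designs", {
  days <- -1:10
  recs <- data.frame(animal_id = rep(c("a", "b"), each = length(days)),
                     day = rep(days, 2), value = 42)
  d <- trajectory_data(recs, variable = "Tcore")
  ini <- init_acclim(d, acclim_control())
  expect_equal(ini$y0, 42, tolerance = 1e-8)
  expect_equal(ini$v1, 0, tolerance = 1e-8)
  expect_equal(ini$v2, 0, tolerance = 1e-8)

  few <- data.frame(animal_id = rep("a", 4), day = c(0, 1, 2, 3), value = 1:4)
  expect_error(init_acclim(trajectory_data(few, variable = "Tcore"),
                           acclim_control()),
               "5 distinct days")
})

test_that("initialiser lands near the true first threshold under realistic noise", {
  d <- sim_preset("Tcore/P1", n = 18, seed = 21)
  ini <- init_acclim(d, acclim_control())
  expect_lt(abs(ini$td1 - 1.46), 1)
})

test_that("fitter recovers exact-model parameters from near-noiseless data", {
  p <- tcore_p1()$params
  days <- -1:10
  set.seed(99)
  recs <- data.frame(animal_id = rep(sprintf("a%d", 1:4), each = length(days)),
                     day = rep(days, 4),
                     value = rep(acclim_curve(p, days), 4) +
                       rnorm(4 * length(days), 0, 1e-6))
  fit <- suppressWarnings(
    fit_acclim(trajectory_data(recs, variable = "Tcore"), fast_control()))
  est <- fit$params_by_group[[1]]
  for (nm in c("y0", "v1", "v2", "td1", "td2")) {
    expect_equal(est[[nm]], p[[nm]], tolerance = 1e-3)
  }
})

test_that("fitted variance vanishes when animals share one profile", {
  pre <- adfi_p1()
  pre$sigma_r2 <- 0
  d <- simulate_trajectories(pre, n_animals = 40, seed = 13)
  fit <- suppressWarnings(fit_acclim(d, fast_control()))
  expect_lt(fit$variance$sigma_r2, 0.05 * fit$variance$sigma_e2)
})

test_that("fit result carries SEs, conditional R2 and convergence diagnostics", {
  d <- sim_preset("Tcore/P1", n = 12, seed = 8)
  fit <- fit_acclim(d, fast_control())
  expect_true(fit$converged)
  expect_false(is.null(fit$se_by_group))
  expect_true(all(fit$se_by_group[[1]] > 0))
  expect_lte(fit$adjusted_r2, 1)
  expect_equal(fit$n_obs, nrow(d))
  expect_equal(fit$n_params, 7)
  expect_gt(fit$n_iterations, 0)
})

test_that("adjusted R2 follows its definition and is unit-invariant", {
  expect_equal(adjusted_r2(0, 450, 216, 12), 1)
  expect_equal(adjusted_r2(450 * (216 - 12 - 1) / (216 - 1), 450, 216, 12), 0)
  expect_equal(adjusted_r2(36, 450, 216, 12), 0.91527, tolerance = 1e-5)
  expect_error(adjusted_r2(36, 450, 13, 12), "n > p")
  # multiplying all observations by c scales sse and ctss by c^2
  c2 <- 3.7^2
  expect_equal(adjusted_r2(36 * c2, 450 * c2, 216, 12),
               adjusted_r2(36, 450, 216, 12))
})

test_that("marginal and conditional predictions behave as defined", {
  d <- sim_preset("Tcore/P1", n = 10, seed = 15)
  fit <- fit_acclim(d, fast_control())
  pm <- predict(fit, days = c(0, 5))
  # population curve at day 0 approximates y0 (td1 well inside the window)
  expect_equal(pm$fit[pm$day == 0], fit$params_by_group[[1]]$y0,
               tolerance = 1e-2)
  pc <- predict(fit, days = c(0, 5), type = "conditional")
  expect_equal(nrow(pc), 2 * 10)
  # conditional = marginal + the animal's empirical-Bayes intercept
  a1 <- pc[pc$animal_id == "A001" & pc$day == 5, "fit"]
  expect_equal(a1, pm$fit[pm$day == 5] + fit$blups[["A001"]])
  expect_warning(predict(fit, days = 12), "extrapolation")
  # shrinkage identity: sum of conditional residual per animal is the
  # marginal sum scaled by sigma_e2/(sigma_e2 + n_i*sigma_r2)
  e_marg <- d$value - acclim_curve(fit$params_by_group[[1]], d$day)
  s_marg <- tapply(e_marg, d$animal_id, sum)
  e_cond <- e_marg - fit$blups[d$animal_id]
  s_cond <- tapply(e_cond, d$animal_id, sum)
  ni <- table(d$animal_id)
  shrink <- fit$variance$sigma_e2 /
    (fit$variance$sigma_e2 + as.numeric(ni) * fit$variance$sigma_r2)
  expect_equal(as.numeric(s_cond), as.numeric(s_marg) * shrink, tolerance = 1e-8)
})

test_that("identical group parameters yield zero Wald statistics", {
  p <- tcore_p1()$params
  fake <- structure(list(
    groups = c("g1", "g2"),
    params_by_group = list(g1 = p, g2 = p),
    vcov = diag(12) * 0.01,
    control = acclim_control()), class = "acclim_fit")
  ct <- compare_acclim_groups(fake)
  expect_true(all(ct$contrasts$z == 0))
  expect_true(all(ct$contrasts$p_value == 1))
  # both groups share a single letter for every parameter
  letters_by_par <- tapply(ct$letters$letter, ct$letters$parameter,
                           function(x) length(unique(x)))
  expect_true(all(letters_by_par == 1))
})

test_that("contrasts are unavailable without a covariance matrix", {
  p <- tcore_p1()$params
  fake <- structure(list(groups = c("g1", "g2"),
                         params_by_group = list(g1 = p, g2 = p),
                         vcov = NULL, control = acclim_control()),
                    class = "acclim_fit")
  expect_error(compare_acclim_groups(fake), "unavailable")
})

test_that("pooling equal groups reproduces the single-group likelihood", {
  p <- tcore_p1()
  d <- sim_preset("Tcore/P1", n = 8, seed = 30)
  d2 <- as.data.frame(d)
  d2$group <- ifelse(d2$animal_id <= "A004", "g1", "g2")
  ll_pooled <- acclim_loglik(p$params, p$sigma_r2, p$sigma_e2, d)
  ll_joint <- acclim_loglik(list(g1 = p$params, g2 = p$params),
                            p$sigma_r2, p$sigma_e2, d2)
  expect_equal(ll_joint, ll_pooled)
})
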