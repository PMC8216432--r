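# Synthetic cohort generator: single-variable trajectory cohorts mirroring the
# stochastic structure the mixed model assumes, and whole-study datasets
# reproducing the 5-group x 3-period challenge design.

#' Simulate a trajectory cohort from a preset
#'
#' Generates `y_ij = Y(d_j; params) + b_i + e_ij` with per-animal intercepts
#' `b_i ~ N(0, sigma_r2)` and residuals `e_ij ~ N(0, sigma_e2)`, mirroring the
#' stochastic structure assumed by [fit_acclim()]. Reproducible given `seed`.
#'
#' @param preset An [acclim_preset()] object (or any list with `params`,
#'   `sigma_r2`, `sigma_e2`, `variable`, `period`).
#' @param n_animals Number of animals (default: the preset's published fit
#'   size).
#' @param days Measurement days (default integer days -1..10).
#' @param seed Mandatory integer seed.
#' @return A [trajectory_data()] object.
#' @export
simulate_trajectories <- function(preset, n_animals = preset$n_animals,
                                  days = preset$day_grid, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (preset$sigma_r2 < 0 || preset$sigma_e2 < 0) {
    stop("variances must be non-negative", call. = FALSE)
  }
  mu <- acclim_curve(preset$params, days)
  nd <- length(days)
  recs <- with_local_seed(seed, {
    b <- stats::rnorm(n_animals, 0, sqrt(preset$sigma_r2))
    eps <- matrix(stats::rnorm(n_animals * nd, 0, sqrt(preset$sigma_e2)),
                  nrow = n_animals)
    data.frame(
      animal_id = rep(sprintf("A%03d", seq_len(n_animals)), each = nd),
      group = if (is.null(preset$group)) "all" else preset$group,
      day = rep(days, n_animals),
      value = rep(mu, n_animals) + rep(b, each = nd) + as.vector(t(eps))
    )
  })
  trajectory_data(recs,
                  variable = if (identical(preset$variable, "Tcore")) "Tcore"
                             else "ADFI_per_kg060",
                  period = if (is.null(preset$period)) NA_character_
                           else preset$period,
                  window = range(days))
}

#' Study design: five treatment groups over three challenge periods
#'
#' Room assignment per group and period (T = thermoneutral at 22 C, H = heat
#' challenge room at 32 C for 5 d): TTT stays thermoneutral throughout; HTT,
#' THT, TTH are challenged in P1, P2, P3 respectively; HHH is challenged in all
#' three periods. Each 15-d period runs from day -3 (prechallenge) through the
#' 5-d challenge (days 0-4) and a recovery phase, with the end-of-period
#' weighing on day 12; challenge onset is day 0.
#'
#' @param n_per_group Animals per treatment group (default 9).
#' @param replicates Number of replicate batches (default 3; animals are split
#'   evenly across replicates).
#' @return A list of class `"study_design"` with `groups`, `rooms` (group x
#'   period matrix of `"T"`/`"H"`), `periods`, `days` (per-period day grid for
#'   daily measurements), `weigh_days`, `n_per_group` and `replicates`.
#' @export
study_design <- function(n_per_group = 9, replicates = 3) {
  groups <- c("TTT", "HTT", "THT", "TTH", "HHH")
  rooms <- rbind(TTT = c("T", "T", "T"),
                 HTT = c("H", "T", "T"),
                 THT = c("T", "H", "T"),
                 TTH = c("T", "T", "H"),
                 HHH = c("H", "H", "H"))
  colnames(rooms) <- c("P1", "P2", "P3")
  structure(list(groups = groups, rooms = rooms,
                 periods = c("P1", "P2", "P3"),
                 days = -3:11, weigh_days = c(-3, 0, 5, 12),
                 n_per_group = n_per_group, replicates = replicates),
            class = "study_design")
}

# Preset labels used for a challenged group in a given period.
challenge_preset_label <- function(group, period, variable) {
  key <- if (variable == "Tcore") "Tcore" else "ADFI"
  if (group == "HHH") return(sprintf("%s/HHH/%s", key, period))
  if (period == "P1") return(sprintf("%s/P1", key))
  sprintf("%s/%s/%s", key, period, group)
}

# Linear interpolation of body weight between within-period weigh days.
interp_bw <- function(weigh_days, bw, days) {
  stats::approx(weigh_days, bw, xout = days, rule = 2)$y
}

#' Simulate a complete challenge study
#'
#' Builds daily feed intake (g/d), daily-mean core temperature (C) and
#' weigh-day body weights (kg) for every animal of a [study_design()]:
#'
#' * Body weight grows linearly from an individual start weight (default mean
#'   68.6 kg, SD 4.3) at `bw_gain` kg/d, with additive weighing noise on the
#'   recorded weigh-day values (gut fill, scale error).
#' * Feed intake is generated on the metabolic scale (g/d/kg^0.60) — flat at
#'   the period's prechallenge level for thermoneutral room-periods, following
#'   the period's challenge preset curve when the group is in the H room — and
#'   multiplied back by interpolated BW^0.60 to emit raw g/d, so downstream
#'   metabolic rescaling is exercised nontrivially.
#' * Core temperature follows a slow linear age drift under thermoneutral
#'   conditions and the period's challenge preset curve during challenges.
#' * Repeatedly challenged (HHH) animals use the attenuated per-period presets,
#'   so acclimation across periods is built in.
#'
#' Per-animal random intercepts (one per variable, persistent across periods)
#' and daily residuals use the first-period pooled variance components.
#'
#' @param design A [study_design()].
#' @param seed Mandatory integer seed.
#' @param r1,r2 Transition smoothness passed to the presets.
#' @param bw_start_mean,bw_start_sd Start-of-study body weight distribution (kg).
#' @param bw_gain Linear growth rate (kg/d).
#' @param bw_noise_sd SD (kg) of additive noise on recorded weigh-day BW
#'   (default `sqrt(0.5)`).
#' @param tcore_tn_ref Thermoneutral core temperature (C) on the day before the
#'   first challenge onset.
#' @param tcore_tn_slope Thermoneutral age drift of core temperature (C/d;
#'   negative = slow decline with age).
#' @return A long data frame of class `"study_data"` with columns `animal_id`,
#'   `group`, `replicate`, `period`, `day`, `variable`
#'   (`ADFI_g_d`, `Tcore_C`, `BW_kg`) and `value`; the seed and design are
#'   attached as attributes.
#' @export
simulate_study <- function(design = study_design(), seed,
                           r1 = 0.25, r2 = 0.25,
                           bw_start_mean = 68.6, bw_start_sd = 4.3,
                           bw_gain = 1.2, bw_noise_sd = sqrt(0.5),
                           tcore_tn_ref = 38.82, tcore_tn_slope = -0.0045) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  groups <- design$groups
  n <- design$n_per_group
  animals <- data.frame(
    animal_id = sprintf("%s%02d", rep(groups, each = n), rep(seq_len(n), length(groups))),
    group = rep(groups, each = n),
    replicate = rep(rep(seq_len(design$replicates), length.out = n), length(groups))
  )
  # shared noise structure: first-period pooled variance components
  adfi_var <- acclim_preset("ADFI/P1", r1, r2)
  tcore_var <- acclim_preset("Tcore/P1", r1, r2)
  # per-period prechallenge metabolic feed level: day -1 value (y0 - v1) of the
  # period's single-challenge preset, shared by all groups in that period
  tn_label <- c(P1 = "ADFI/P1", P2 = "ADFI/P2/THT", P3 = "ADFI/P3/TTH")
  adfi_tn <- vapply(design$periods, function(pd) {
    p <- acclim_preset(tn_label[[pd]], r1, r2)$params
    p$y0 - p$v1
  }, numeric(1))
  names(adfi_tn) <- design$periods

  with_local_seed(seed, {
    na <- nrow(animals)
    bw0 <- stats::rnorm(na, bw_start_mean, bw_start_sd)
    b_adfi <- stats::rnorm(na, 0, sqrt(adfi_var$sigma_r2))
    b_tcore <- stats::rnorm(na, 0, sqrt(tcore_var$sigma_r2))
    rows <- vector("list", na * length(design$periods))
    k <- 0
    for (i in seq_len(na)) {
      g <- animals$group[i]
      for (pd_i in seq_along(design$periods)) {
        pd <- design$periods[pd_i]
        abs0 <- 15 * (pd_i - 1)                      # abs day of period day -3
        abs_days <- abs0 + design$days + 3           # daily measurement days
        abs_weigh <- abs0 + design$weigh_days + 3
        challenged <- design$rooms[g, pd] == "H"

        # body weight: linear growth, noisy at weigh days
        bw_true_weigh <- bw0[i] + bw_gain * abs_weigh
        bw_rec <- bw_true_weigh + stats::rnorm(length(abs_weigh), 0, bw_noise_sd)
        bw_daily <- interp_bw(design$weigh_days, bw_rec, design$days)

        # feed intake on the metabolic scale
        if (challenged) {
          pp <- acclim_preset(challenge_preset_label(g, pd, "ADFI"), r1, r2)
          m <- ifelse(design$days >= -1,
                      acclim_curve(pp$params, design$days),
                      pp$params$y0 - pp$params$v1)
        } else {
          m <- rep(adfi_tn[[pd]], length(design$days))
        }
        m_obs <- m + b_adfi[i] +
          stats::rnorm(length(design$days), 0, sqrt(adfi_var$sigma_e2))
        feed <- m_obs * bw_daily^0.60

        # core temperature
        tn <- tcore_tn_ref + tcore_tn_slope * (abs_days - 2)
        if (challenged) {
          tp <- acclim_preset(challenge_preset_label(g, pd, "Tcore"), r1, r2)
          tc_mean <- ifelse(design$days >= -1,
                            acclim_curve(tp$params, design$days), tn)
        } else {
          tc_mean <- tn
        }
        tc <- tc_mean + b_tcore[i] +
          stats::rnorm(length(design$days), 0, sqrt(tcore_var$sigma_e2))

        k <- k + 1
        rows[[k]] <- data.frame(
          animal_id = animals$animal_id[i], group = g,
          replicate = animals$replicate[i], period = pd,
          day = c(design$days, design$days, design$weigh_days),
          variable = c(rep("ADFI_g_d", length(design$days)),
                       rep("Tcore_C", length(design$days)),
                       rep("BW_kg", length(abs_weigh))),
          value = c(feed, tc, bw_rec)
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- seed
    attr(out, "design") <- design
    class(out) <- c("study_data", "data.frame")
    out
  })
}
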