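# Data preparation and descriptive performance computations: analysis pools,
# interval performance (ADFI, ADG, feed:gain), metabolic scaling, daily
# averaging of continuous records, percent-change summaries.

#' Analysis pools per period
#'
#' Maps the five treatment groups to the analysis pools used within each
#' period: groups sharing the same room history up to and including that
#' period's challenge are pooled.
#'
#' @param period `"P1"`, `"P2"` or `"P3"`.
#' @return A named character vector mapping each treatment group to its pool
#'   label.
#' @examples
#' assign_pools("P1")
#' @export
assign_pools <- function(period) {
  switch(period,
    P1 = c(TTT = "T", THT = "T", TTH = "T", HTT = "H", HHH = "H"),
    P2 = c(TTT = "TT&HT", TTH = "TT&HT", HTT = "TT&HT", THT = "TH", HHH = "HH"),
    P3 = c(TTT = "TTT&HTT&THT", HTT = "TTT&HTT&THT", THT = "TTT&HTT&THT",
           TTH = "TTH", HHH = "HHH"),
    stop("unknown period: ", period, call. = FALSE)
  )
}

#' Interval growth performance from a study dataset
#'
#' Splits each period into the intervals `[-3, 0)` (prechallenge), `[0, 5)`
#' (challenge) and `[5, 12)` (recovery) and computes, per analysis pool:
#' average daily feed intake (g/d), average daily gain (g/d, from the boundary
#' body weights) and the feed:gain ratio (kg feed per kg gain). Feed is
#' attributed to the day it was offered; interval boundaries use the weigh-day
#' body weights (days -3, 0, 5 and the end-of-period weighing on day 12).
#' Intervals with non-positive weight gain have an undefined feed:gain ratio
#' and are flagged; so are intervals missing a boundary weight.
#'
#' @param study A `"study_data"` long data frame (see [simulate_study()]).
#' @param period Period to summarise (`"P1"`, `"P2"`, `"P3"`).
#' @param by_animal If `TRUE`, return per-animal rows instead of pool means.
#' @return A data frame with columns `pool`, `period`, `interval`, `adfi`,
#'   `adg`, `fg`, `n_animals`, `flagged`.
#' @export
interval_performance <- function(study, period, by_animal = FALSE) {
  pools <- assign_pools(period)
  sub <- study[study$period == period, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records for period ", period, call. = FALSE)
  intervals <- list(`[-3,0)` = c(-3, 0), `[0,5)` = c(0, 5), `[5,12)` = c(5, 12))
  feed <- sub[sub$variable == "ADFI_g_d", ]
  bw <- sub[sub$variable == "BW_kg", ]
  animals <- unique(sub[, c("animal_id", "group")])
  rows <- list()
  for (a_i in seq_len(nrow(animals))) {
    a <- animals$animal_id[a_i]
    pool <- pools[[animals$group[a_i]]]
    fa <- feed[feed$animal_id == a, ]
    ba <- bw[bw$animal_id == a, ]
    for (iv in names(intervals)) {
      lim <- intervals[[iv]]
      len <- lim[2] - lim[1]
      fd <- fa$value[fa$day >= lim[1] & fa$day < lim[2]]
      bw_start <- ba$value[abs(ba$day - lim[1]) < 1e-8]
      bw_end <- ba$value[abs(ba$day - lim[2]) < 1e-8]
      flagged <- FALSE
      adfi <- if (length(fd)) mean(fd) else {flagged <- TRUE; NA_real_}
      if (length(bw_start) == 1 && length(bw_end) == 1) {
        gain <- bw_end - bw_start
        adg <- 1000 * gain / len
        fg <- if (gain > 0) (adfi * len / 1000) / gain else {flagged <- TRUE; NA_real_}
      } else {
        flagged <- TRUE
        adg <- NA_real_
        fg <- NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        pool = pool, period = period, interval = iv, animal_id = a,
        adfi = adfi, adg = adg, fg = fg, flagged = flagged)
    }
  }
  per_animal <- do.call(rbind, rows)
  if (by_animal) return(per_animal)
  agg <- do.call(rbind, lapply(split(per_animal,
                                     list(per_animal$pool, per_animal$interval),
                                     drop = TRUE), function(df) {
    data.frame(pool = df$pool[1], period = period, interval = df$interval[1],
               adfi = mean(df$adfi, na.rm = TRUE),
               adg = mean(df$adg, na.rm = TRUE),
               fg = mean(df$fg, na.rm = TRUE),
               n_animals = length(unique(df$animal_id)),
               flagged = any(df$flagged))
  }))
  agg <- agg[order(agg$pool, agg$interval), ]
  rownames(agg) <- NULL
  agg
}

#' Percent change of performance relative to a prechallenge reference
#'
#' `100 * (pre - during) / pre`: positive for decreases. By default the result
#' is rounded to the nearest integer percent, half away from zero, as used for
#' reported performance summaries.
#'
#' @param pre Reference (prechallenge) value, > 0.
#' @param during Value during the challenge.
#' @param rounded Round to the nearest integer percent (half away from zero)?
#' @return Percent change (vectorised).
#' @examples
#' percent_change(1351, 376)  # 72
#' @export
percent_change <- function(pre, during, rounded = TRUE) {
  if (any(pre <= 0)) stop("reference value must be positive", call. = FALSE)
  pc <- 100 * (pre - during) / pre
  if (rounded) sign(pc) * floor(abs(pc) + 0.5) else pc
}

#' Scale feed intake by metabolic body weight
#'
#' @param feed Feed intake (g/d).
#' @param bw Body weight (kg), > 0 (typically linearly interpolated to the
#'   feed day from the weigh-day records).
#' @return Feed intake in g/d/kg^0.60.
#' @export
metabolic_scale <- function(feed, bw) {
  if (any(!is.finite(bw)) || any(bw <= 0)) {
    stop("body weight must be positive and finite", call. = FALSE)
  }
  feed / bw^0.60
}

#' Metabolic-scale feed intake trajectories from a study dataset
#'
#' Converts the raw daily feed records of a study dataset into the metabolic
#' scale (g/d/kg^0.60), dividing each day's intake by the interpolated body
#' weight (linear between weigh days) raised to the power 0.60.
#'
#' @param study A `"study_data"` long data frame.
#' @return A data frame like the feed rows of `study`, with
#'   `variable = "ADFI_g_d_kg060"` and rescaled `value`.
#' @export
metabolic_scale_study <- function(study) {
  feed <- study[study$variable == "ADFI_g_d", , drop = FALSE]
  bw <- study[study$variable == "BW_kg", , drop = FALSE]
  out <- feed
  for (a in unique(feed$animal_id)) {
    for (pd in unique(feed$period[feed$animal_id == a])) {
      fi <- which(out$animal_id == a & out$period == pd)
      bi <- bw[bw$animal_id == a & bw$period == pd, ]
      bwd <- interp_bw(bi$day, bi$value, out$day[fi])
      out$value[fi] <- metabolic_scale(out$value[fi], bwd)
    }
  }
  out$variable <- "ADFI_g_d_kg060"
  out
}

#' Daily averages of continuous (sub-daily) records
#'
#' Averages sub-daily sensor readings (e.g. core temperature logged every few
#' minutes) into one value per animal per day. Days with fewer readings than
#' `min_readings` are flagged; empty days are simply absent.
#'
#' @param records A data frame with columns `animal_id`, `time` (numeric days,
#'   fractional part = time of day) and `value`.
#' @param min_readings Minimum readings per day below which the daily mean is
#'   flagged as low coverage.
#' @return A data frame with `animal_id`, `day`, `value` (daily mean),
#'   `n_readings` and `flagged`.
#' @export
daily_average <- function(records, min_readings = 1) {
  stopifnot(all(c("animal_id", "time", "value") %in% names(records)))
  day <- floor(records$time)
  key <- interaction(records$animal_id, day, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(df) {
    data.frame(animal_id = df$animal_id[1], day = floor(df$time[1]),
               value = mean(df$value), n_readings = nrow(df),
               flagged = nrow(df) < min_readings)
  }))
  out <- out[order(out$animal_id, out$day), ]
  rownames(out) <- NULL
  out
}
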