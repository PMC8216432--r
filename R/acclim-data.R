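# Long-format trajectory container used by the likelihood and the fitter.

#' Long-format trajectory dataset for one response variable
#'
#' Validates and classes a long-format table of daily observations (one row per
#' animal x day) of a single response variable around a heat challenge.
#'
#' @param records A data frame with columns `animal_id`, `day`, `value`, and
#'   optionally `group` (defaults to a single group `"all"`).
#' @param variable One of `"ADFI_per_kg060"` (feed intake scaled by metabolic
#'   body weight, g/d/kg^0.60) or `"Tcore"` (daily-mean core temperature, C).
#' @param period Optional period label (e.g. `"P1"`).
#' @param window Fit window in days relative to challenge onset; observations
#'   must fall inside it.
#' @return The records as a data frame of class `"trajectory_data"`, with
#'   attributes `variable`, `period` and `window`.
#' @export
trajectory_data <- function(records, variable = c("ADFI_per_kg060", "Tcore"),
                            period = NA_character_, window = c(-1, 10)) {
  variable <- match.arg(variable)
  records <- as.data.frame(records)
  needed <- c("animal_id", "day", "value")
  if (!all(needed %in% names(records))) {
    stop("records must have columns animal_id, day, value", call. = FALSE)
  }
  if (!"group" %in% names(records)) records$group <- "all"
  records$animal_id <- as.character(records$animal_id)
  records$group <- as.character(records$group)
  if (!all(is.finite(records$day)) || !all(is.finite(records$value))) {
    stop("days and values must all be finite", call. = FALSE)
  }
  eps <- 1e-8
  if (any(records$day < window[1] - eps | records$day > window[2] + eps)) {
    stop(sprintf("all days must lie within the fit window [%g, %g]",
                 window[1], window[2]), call. = FALSE)
  }
  ndays <- tapply(records$day, records$animal_id, function(d) length(unique(d)))
  if (any(ndays < 3)) {
    stop("every animal must contribute at least 3 distinct days", call. = FALSE)
  }
  grp_per_animal <- tapply(records$group, records$animal_id,
                           function(g) length(unique(g)))
  if (any(grp_per_animal > 1)) {
    stop("each animal must belong to a single group", call. = FALSE)
  }
  out <- records[, c("animal_id", "group", "day", "value")]
  attr(out, "variable") <- variable
  attr(out, "period") <- period
  attr(out, "window") <- window
  class(out) <- c("trajectory_data", "data.frame")
  out
}

#' @export
print.trajectory_data <- function(x, ...) {
  cat(sprintf("Trajectory dataset: %s%s, %d animals, %d observations, days %g..%g\n",
              attr(x, "variable"),
              if (is.na(attr(x, "period"))) "" else paste0(" (", attr(x, "period"), ")"),
              length(unique(x$animal_id)), nrow(x), min(x$day), max(x$day)))
  NextMethod()
}
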