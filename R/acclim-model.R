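# Two-threshold smooth broken-line response model.
#
# The mean trajectory of a response Y (feed intake on the metabolic scale, or
# daily-mean core temperature) around a heat challenge starting at day 0 is
#
#   Y(d) = y0 + v1*d - r1*(v1 - v2)*softplus((d - td1)/r1)
#               - r2*v2*softplus((d - td2)/r2)
#
# with softplus(x) = log(1 + exp(x)).  The curve is linear with slope v1 before
# the first threshold day td1, slope v2 between td1 and td2, and slope 0 after
# td2; r1, r2 (> 0, in days) set the width of the smooth transitions.  As
# r1, r2 -> 0 the curve converges to the piecewise-linear broken stick through
# (0, y0).

#' Parameters of the two-threshold acclimation trajectory
#'
#' Constructs and validates the parameter set of the smooth broken-line mean
#' function used to describe biphasic responses to a heat challenge: a linear
#' change at rate `v1` up to the first threshold day `td1` (short-term
#' response), a second linear phase at rate `v2` up to `td2` (acclimation
#' phase), and a plateau afterwards.
#'
#' @param y0 Response value at day 0 (challenge onset), in response units
#'   (g/d/kg^0.60 for scaled feed intake, degrees C for core temperature).
#' @param v1 Slope before `td1` (units/d).
#' @param v2 Slope between `td1` and `td2` (units/d).
#' @param td1,td2 First and second threshold days, relative to challenge onset;
#'   `td1 < td2` is required.
#' @param r1,r2 Smoothness (d, strictly positive) of the transitions at `td1`
#'   and `td2`. Small values approach sharp breakpoints.
#'
#' @return An object of class `"acclim_params"` (a named list of the seven
#'   parameters).
#' @examples
#' p <- acclim_params(y0 = 39.3, v1 = 0.48, v2 = -0.30, td1 = 1.46, td2 = 6.30)
#' acclim_curve(p, 0:10)
#' @export
acclim_params <- function(y0, v1, v2, td1, td2, r1 = 0.25, r2 = 0.25) {
  vals <- c(y0[1], v1[1], v2[1], td1[1], td2[1], r1[1], r2[1])
  names(vals) <- c("y0", "v1", "v2", "td1", "td2", "r1", "r2")
  if (length(vals) != 7L || !all(is.finite(vals))) {
    stop("all seven parameters must be finite scalars", call. = FALSE)
  }
  if (r1 <= 0 || r2 <= 0) {
    stop("smoothing parameters r1 and r2 must be strictly positive", call. = FALSE)
  }
  if (td1 >= td2) {
    stop("td1 must be strictly smaller than td2", call. = FALSE)
  }
  structure(as.list(vals), class = "acclim_params")
}

#' @export
print.acclim_params <- function(x, digits = 4, ...) {
  cat("Two-threshold acclimation parameters:\n")
  print(round(unlist(x), digits))
  invisible(x)
}

as_acclim_params <- function(x) {
  if (inherits(x, "acclim_params")) return(x)
  x <- as.list(x)
  do.call(acclim_params, x[c("y0", "v1", "v2", "td1", "td2", "r1", "r2")])
}

# Overflow-safe log(1 + exp(x)): for x > 0 use x + log1p(exp(-x)).
softplus <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

#' Evaluate the smooth acclimation trajectory
#'
#' Computes the mean response at day(s) `d`. Numerically stable for arbitrarily
#' sharp transitions (small `r1`, `r2`).
#'
#' @param params An [acclim_params()] object.
#' @param d Numeric vector of days relative to challenge onset.
#' @return Numeric vector of mean responses, same length as `d`.
#' @seealso [acclim_curve_sharp()] for the piecewise-linear limit,
#'   [acclim_slope()] for the derivative in `d`.
#' @export
acclim_curve <- function(params, d) {
  p <- as_acclim_params(params)
  stopifnot(is.numeric(d))
  p$y0 + p$v1 * d -
    p$r1 * (p$v1 - p$v2) * softplus((d - p$td1) / p$r1) -
    p$r2 * p$v2 * softplus((d - p$td2) / p$r2)
}

#' Piecewise-linear (sharp-breakpoint) limit of the acclimation trajectory
#'
#' The exact r1, r2 -> 0 limit of [acclim_curve()]: slope `v1` for `d < td1`,
#' slope `v2` on `[td1, td2)`, slope 0 afterwards, anchored so the first
#' segment passes through `(0, y0)`. Used as an analytic verification oracle
#' for the smooth model and for trajectory summaries.
#'
#' @inheritParams acclim_curve
#' @return Numeric vector of responses.
#' @export
acclim_curve_sharp <- function(params, d) {
  p <- as.list(params)
  if (!is.numeric(p$td1) || !is.numeric(p$td2) || p$td1 >= p$td2) {
    stop("td1 must be strictly smaller than td2", call. = FALSE)
  }
  p$y0 + p$v1 * pmin(d, p$td1) + p$v2 * (pmin(pmax(d, p$td1), p$td2) - p$td1)
}

#' Slope of the smooth acclimation trajectory
#'
#' Analytic derivative dY/dd of [acclim_curve()]:
#' `v1 - (v1 - v2) * plogis((d - td1)/r1) - v2 * plogis((d - td2)/r2)`.
#' When the thresholds are well separated relative to `r1`, `r2` the slope
#' tends to `v1` before `td1`, `v2` between the thresholds and 0 after `td2`.
#'
#' @inheritParams acclim_curve
#' @return Numeric vector of slopes (units/d).
#' @export
acclim_slope <- function(params, d) {
  p <- as_acclim_params(params)
  p$v1 - (p$v1 - p$v2) * stats::plogis((d - p$td1) / p$r1) -
    p$v2 * stats::plogis((d - p$td2) / p$r2)
}

#' Gradient of the trajectory with respect to its mean parameters
#'
#' Analytic partial derivatives of [acclim_curve()] with respect to
#' `(y0, v1, v2, td1, td2)`, with `r1`, `r2` held fixed. Used by the fitter
#' and checked against central finite differences in the test suite.
#'
#' @inheritParams acclim_curve
#' @return A numeric matrix with `length(d)` rows and columns
#'   `y0`, `v1`, `v2`, `td1`, `td2`.
#' @export
acclim_gradient <- function(params, d) {
  p <- as_acclim_params(params)
  z1 <- (d - p$td1) / p$r1
  z2 <- (d - p$td2) / p$r2
  sp1 <- softplus(z1)
  sp2 <- softplus(z2)
  cbind(
    y0  = rep(1, length(d)),
    v1  = d - p$r1 * sp1,
    v2  = p$r1 * sp1 - p$r2 * sp2,
    td1 = (p$v1 - p$v2) * stats::plogis(z1),
    td2 = p$v2 * stats::plogis(z2)
  )
}

#' Trajectory summaries on the sharp-breakpoint limit
#'
#' Derived quantities of the fitted trajectory, computed on the piecewise-linear
#' limit where they are unambiguous: the extremum value attained at `td1` (a
#' trough when `v1 < 0 < v2`, as for feed intake; a peak when `v1 > 0 > v2`, as
#' for core temperature), the earliest day at which the minimum (and maximum)
#' over the window is attained, and the contrast between the end of the window
#' and day -1 (the prechallenge reference day).
#'
#' Because the sharp curve is flat after `td2`, a minimum reached during the
#' declining second phase is attained earliest at `td2`; this makes `td2` the
#' day at which core temperature reaches its minimum.
#'
#' @param params An [acclim_params()] object (only the breakpoint geometry is
#'   used; `r1`, `r2` are ignored).
#' @param window Numeric length-2 vector `c(day_lo, day_hi)` of the evaluation
#'   window; must contain both thresholds for the summaries to be defined.
#' @return A list with elements `defined` (logical), `extremum_value`,
#'   `extremum_day` (= `td1`), `extremum_type` (`"peak"`, `"trough"` or
#'   `"none"`), `min_day`, `min_value`, `max_day`, `max_value`, and `contrast`
#'   (= Y(day_hi) - Y(-1)).
#' @export
acclim_summaries <- function(params, window = c(-1, 10)) {
  p <- as.list(params)
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) stop("window must satisfy day_lo < day_hi", call. = FALSE)
  if (p$td1 < lo || p$td2 > hi) {
    return(list(defined = FALSE, extremum_value = NA_real_,
                extremum_day = NA_real_, extremum_type = "undefined",
                min_day = NA_real_, min_value = NA_real_,
                max_day = NA_real_, max_value = NA_real_,
                contrast = NA_real_))
  }
  # Piecewise-linear: extrema over the window occur at the candidate days
  # below; the value at day_hi always equals the value at td2 (zero terminal
  # slope), so td2 is the earliest representative of the plateau.
  cand <- c(lo, p$td1, p$td2)
  vals <- acclim_curve_sharp(p, cand)
  tol <- 1e-9 * max(1, abs(vals))
  i_min <- which(vals <= min(vals) + tol)[1]
  i_max <- which(vals >= max(vals) - tol)[1]
  extremum_type <- if (p$v1 > 0 && p$v2 < 0) "peak"
                   else if (p$v1 < 0 && p$v2 > 0) "trough"
                   else "none"
  list(
    defined = TRUE,
    extremum_value = acclim_curve_sharp(p, p$td1),
    extremum_day = p$td1,
    extremum_type = extremum_type,
    min_day = cand[i_min], min_value = vals[i_min],
    max_day = cand[i_max], max_value = vals[i_max],
    contrast = acclim_curve_sharp(p, hi) - acclim_curve_sharp(p, -1)
  )
}
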