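# Marginal likelihood of the nonlinear mixed model.
#
# Per animal i the model is  y_ij = Y(d_ij; theta_g(i)) + b_i + e_ij  with
# b_i ~ N(0, sigma_r2) and e_ij ~ N(0, sigma_e2).  Because the random intercept
# is additive Gaussian, the marginal distribution of each animal's vector is
# multivariate normal with compound-symmetry covariance
# sigma_e2 * I + sigma_r2 * J, and the marginal log-likelihood has a closed
# form.  An adaptive Gauss-Hermite quadrature path is kept as an independent
# cross-check (it integrates the Gaussian integrand exactly for any number of
# nodes, so agreement with the closed form is a sharp correctness test).

# Resolve per-record mean values given single params or a named list per group.
acclim_mean_values <- function(params, data) {
  if (inherits(params, "acclim_params") ||
      (!is.null(names(params)) && all(c("y0", "td1") %in% names(params)))) {
    return(acclim_curve(params, data$day))
  }
  if (is.null(names(params)) || !all(unique(data$group) %in% names(params))) {
    stop("params must be an acclim_params object or a named list covering every group",
         call. = FALSE)
  }
  mu <- numeric(nrow(data))
  for (g in unique(data$group)) {
    idx <- data$group == g
    mu[idx] <- acclim_curve(params[[g]], data$day[idx])
  }
  mu
}

#' Marginal log-likelihood of the random-intercept acclimation model
#'
#' Computes the log-likelihood of a [trajectory_data()] set under the
#' two-threshold mean function with a per-animal Gaussian random intercept
#' (variance `sigma_r2`) and Gaussian residuals (variance `sigma_e2`), with the
#' random effect integrated out.
#'
#' @param params Either a single [acclim_params()] object (one group) or a
#'   named list of them, one per group label appearing in `data`.
#' @param sigma_r2 Between-animal random-intercept variance (units^2), >= 0.
#' @param sigma_e2 Residual variance (units^2), > 0.
#' @param data A [trajectory_data()] object (or data frame with `animal_id`,
#'   `group`, `day`, `value`).
#' @param method `"closed"` for the exact compound-symmetry form (default),
#'   `"agq"` for adaptive Gauss-Hermite quadrature.
#' @param nodes Number of quadrature nodes for `method = "agq"`.
#' @return The scalar marginal log-likelihood.
#' @export
acclim_loglik <- function(params, sigma_r2, sigma_e2, data,
                          method = c("closed", "agq"), nodes = 9) {
  method <- match.arg(method)
  if (!is.finite(sigma_r2) || sigma_r2 < 0) {
    stop("sigma_r2 must be finite and non-negative", call. = FALSE)
  }
  if (!is.finite(sigma_e2) || sigma_e2 <= 0) {
    stop("sigma_e2 must be strictly positive (degenerate likelihood otherwise)",
         call. = FALSE)
  }
  e <- data$value - acclim_mean_values(params, data)
  id <- factor(data$animal_id)
  S1 <- tapply(e, id, sum)
  S2 <- tapply(e^2, id, sum)
  ni <- tabulate(id)

  if (method == "closed" || sigma_r2 == 0) {
    tau <- sigma_e2 + ni * sigma_r2
    quad <- (S2 - sigma_r2 * S1^2 / tau) / sigma_e2
    ll <- -0.5 * (ni * log(2 * pi) + (ni - 1) * log(sigma_e2) + log(tau) + quad)
    return(sum(ll))
  }

  gh <- pracma::gaussHermite(nodes)
  sd_e <- sqrt(sigma_e2)
  sd_r <- sqrt(sigma_r2)
  ll <- 0
  for (i in seq_along(ni)) {
    ei <- e[id == levels(id)[i]]
    n_i <- ni[i]
    # Adaptive centring at the conditional posterior mode and scale of b_i.
    m <- sigma_r2 * S1[i] / (n_i * sigma_r2 + sigma_e2)
    s <- sqrt(1 / (n_i / sigma_e2 + 1 / sigma_r2))
    b <- m + sqrt(2) * s * gh$x
    logf <- vapply(b, function(bk) {
      sum(stats::dnorm(ei - bk, sd = sd_e, log = TRUE)) +
        stats::dnorm(bk, sd = sd_r, log = TRUE)
    }, numeric(1))
    logf <- logf + gh$x^2
    mx <- max(logf)
    ll <- ll + mx + log(sum(gh$w * exp(logf - mx)) * sqrt(2) * s)
  }
  as.numeric(ll)
}

# Empirical-Bayes (BLUP) random intercepts given marginal residuals e.
acclim_blups <- function(e, id, sigma_r2, sigma_e2) {
  id <- factor(id)
  S1 <- tapply(e, id, sum)
  ni <- tabulate(id)
  b <- sigma_r2 * S1 / (ni * sigma_r2 + sigma_e2)
  stats::setNames(as.numeric(b), levels(id))
}
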