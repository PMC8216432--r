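# Maximum-likelihood fitting of the two-threshold nonlinear mixed model.

#' Control settings for the acclimation model fitter
#'
#' @param r1,r2 Fixed transition smoothness in days (shared across groups;
#'   assumed unaffected by temperature). Default 0.25 d.
#' @param profile_r If `TRUE`, refit over `r_grid` with `r1 = r2 = r` and keep
#'   the value maximising the log-likelihood.
#' @param r_grid Candidate smoothness values for profiling.
#' @param bounds Length-2 vector: box bounds for both threshold days. The
#'   default lower bound of 0 reflects that the thresholds are days of
#'   exposure (non-negative by definition) and that, on a daily grid starting
#'   at day -1, a threshold below 0 would leave a single observed day on the
#'   first segment, making its slope unidentifiable.
#' @param min_gap Smallest allowed `td2 - td1` (a smooth quadratic penalty
#'   keeps the optimiser away from coincident thresholds).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param maxit Maximum optimiser iterations.
#' @param multistart Number of starts (first from the lattice initialiser, the
#'   rest from jittered copies of it).
#' @param seed Seed for the multi-start jitter (local to the fitter).
#' @param nodes Quadrature nodes used when cross-checking the likelihood.
#' @param alpha Significance level for group contrasts.
#' @param lattice Lattice step (d) of the threshold grid search initialiser.
#' @return A list of class `"acclim_control"`.
#' @export
acclim_control <- function(r1 = 0.25, r2 = 0.25, profile_r = FALSE,
                           r_grid = c(0.05, 0.1, 0.25, 0.5, 1.0),
                           bounds = c(0, 10), min_gap = 0.1,
                           reltol = 1e-8, maxit = 500, multistart = 5,
                           seed = 1L, nodes = 9, alpha = 0.05, lattice = 0.25) {
  stopifnot(r1 > 0, r2 > 0, length(bounds) == 2, bounds[1] < bounds[2],
            min_gap > 0, multistart >= 1)
  structure(list(r1 = r1, r2 = r2, profile_r = profile_r, r_grid = r_grid,
                 bounds = bounds, min_gap = min_gap, reltol = reltol,
                 maxit = maxit, multistart = multistart, seed = seed,
                 nodes = nodes, alpha = alpha, lattice = lattice),
            class = "acclim_control")
}

# Evaluate a block of code with a temporary RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Sharp-limit regression basis for fixed thresholds: Y is linear in
# (y0, v1, v2) given (td1, td2).
sharp_basis <- function(d, td1, td2) {
  cbind(1, pmin(d, td1), pmin(pmax(d, td1), td2) - td1)
}

#' Lattice initialiser for the acclimation model
#'
#' Grid search over threshold-day pairs on a regular lattice, solving the
#' profiled ordinary least-squares problem in `(y0, v1, v2)` on the sharp-limit
#' basis at each pair, and returning the lattice minimiser of the residual sum
#' of squares.
#'
#' @param data A [trajectory_data()] object (single group).
#' @param control An [acclim_control()] object (supplies `r1`, `r2`, `bounds`
#'   and the lattice step).
#' @return An [acclim_params()] object.
#' @export
init_acclim <- function(data, control = acclim_control()) {
  d <- data$day
  y <- data$value
  if (length(unique(d)) < 5) {
    stop("need at least 5 distinct days to initialise 5 mean parameters",
         call. = FALSE)
  }
  grid <- seq(control$bounds[1], control$bounds[2], by = control$lattice)
  best <- NULL
  best_sse <- Inf
  for (i in seq_len(length(grid) - 1)) {
    for (j in seq(i + 1, length(grid))) {
      X <- sharp_basis(d, grid[i], grid[j])
      fit <- stats::lm.fit(X, y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      sse <- sum((y - X %*% beta)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best <- list(beta = beta, td1 = grid[i], td2 = grid[j])
      }
    }
  }
  acclim_params(y0 = best$beta[1], v1 = best$beta[2], v2 = best$beta[3],
                td1 = best$td1, td2 = best$td2,
                r1 = control$r1, r2 = control$r2)
}

# Moment starting values for the variance components from OLS residuals.
init_variances <- function(resid, id) {
  id <- factor(id)
  within_var <- mean(tapply(resid, id, stats::var), na.rm = TRUE)
  if (!is.finite(within_var) || within_var <= 0) within_var <- stats::var(resid)
  mean_by <- tapply(resid, id, mean)
  nbar <- mean(tabulate(id))
  between <- max(stats::var(as.numeric(mean_by)) - within_var / nbar,
                 0.05 * within_var)
  c(sigma_r2 = between, sigma_e2 = max(within_var, 1e-10))
}

pack_par <- function(params_by_group, sigma_r2, sigma_e2) {
  c(unlist(lapply(params_by_group, function(p)
    unlist(p[c("y0", "v1", "v2", "td1", "td2")]))),
    log_sr2 = log(max(sigma_r2, 1e-12)), log_se2 = log(sigma_e2))
}

unpack_par <- function(par, groups, r1, r2) {
  k <- length(groups)
  params <- vector("list", k)
  names(params) <- groups
  for (i in seq_len(k)) {
    th <- par[(5 * (i - 1) + 1):(5 * i)]
    params[[i]] <- list(y0 = th[1], v1 = th[2], v2 = th[3],
                        td1 = th[4], td2 = th[5], r1 = r1, r2 = r2)
  }
  list(params = params,
       sigma_r2 = exp(par[5 * k + 1]), sigma_e2 = exp(par[5 * k + 2]))
}

#' Fit the two-threshold nonlinear mixed model
#'
#' Maximises the closed-form marginal likelihood of [acclim_loglik()] over the
#' per-group mean parameters `(y0, v1, v2, td1, td2)` and the shared variance
#' components `(sigma_r2, sigma_e2)`, with `r1`, `r2` fixed (or profiled over a
#' grid). Threshold days are estimated on the natural scale under box
#' constraints; variances are optimised on the log scale. Standard errors come
#' from the inverse observed information (finite-difference Hessian), and the
#' adjusted R-squared is computed from conditional residuals (observed minus
#' predicted with the empirical-Bayes animal intercepts plugged in).
#'
#' @param data A [trajectory_data()] object; one parameter set is estimated per
#'   group label present in the data.
#' @param control An [acclim_control()] object.
#' @return An object of class `"acclim_fit"` with elements `params_by_group`,
#'   `variance` (`sigma_r2`, `sigma_e2`), `se_by_group`, `vcov`, `loglik`,
#'   `n_obs`, `n_params`, `adjusted_r2`, `converged`, `n_iterations`,
#'   `boundary_warning`, `blups`, plus the data and control used.
#' @export
fit_acclim <- function(data, control = acclim_control()) {
  if (!inherits(data, "trajectory_data")) {
    data <- trajectory_data(data)
  }
  if (isTRUE(control$profile_r)) {
    fits <- lapply(control$r_grid, function(r) {
      ctl <- control
      ctl$r1 <- r; ctl$r2 <- r; ctl$profile_r <- FALSE
      fit_acclim(data, ctl)
    })
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    best$profiled_r <- best$control$r1
    return(best)
  }

  groups <- sort(unique(data$group))
  k <- length(groups)
  inits <- lapply(groups, function(g) {
    init_acclim(data[data$group == g, , drop = FALSE], control)
  })
  names(inits) <- groups

  # OLS residuals for variance starting values
  mu0 <- acclim_mean_values(inits, data)
  v0 <- init_variances(data$value - mu0, data$animal_id)

  lo <- control$bounds[1]; hi <- control$bounds[2]
  lower <- c(rep(c(-Inf, -Inf, -Inf, lo, lo), k), -30, -30)
  upper <- c(rep(c(Inf, Inf, Inf, hi, hi), k), 30, 30)

  negll <- function(par) {
    u <- unpack_par(par, groups, control$r1, control$r2)
    pen <- 0
    for (p in u$params) {
      gap <- p$td2 - p$td1
      if (gap < control$min_gap) pen <- pen + 1e4 * (control$min_gap - gap)^2
    }
    ll <- tryCatch(
      acclim_loglik(u$params, u$sigma_r2, u$sigma_e2, data, method = "closed"),
      error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    -ll + pen
  }

  par0 <- pack_par(inits, v0["sigma_r2"], v0["sigma_e2"])
  starts <- list(par0)
  if (control$multistart > 1) {
    with_local_seed(control$seed, {
      for (s in seq_len(control$multistart - 1)) {
        p <- par0
        idx_mean <- seq_len(5 * k)
        p[idx_mean] <- p[idx_mean] * (1 + stats::rnorm(5 * k, 0, 0.05))
        td_idx <- as.vector(outer(c(4, 5), 5 * (seq_len(k) - 1), `+`))
        p[td_idx] <- pmin(pmax(p[td_idx] + stats::runif(length(td_idx), -0.75, 0.75),
                               lo + 0.01), hi - 0.01)
        # keep td1 < td2 within each group
        for (i in seq_len(k)) {
          a <- 5 * (i - 1)
          if (p[a + 4] >= p[a + 5]) {
            mid <- mean(p[c(a + 4, a + 5)])
            p[a + 4] <- mid - control$min_gap
            p[a + 5] <- mid + control$min_gap
          }
        }
        starts[[s + 1]] <- p
      }
    })
  }

  runs <- lapply(starts, function(p0) {
    stats::nlminb(p0, negll, lower = lower, upper = upper,
                  control = list(rel.tol = control$reltol,
                                 iter.max = control$maxit,
                                 eval.max = 10 * control$maxit))
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  norms <- vapply(runs, function(r) sum(r$par^2), numeric(1))
  best_i <- order(objs, norms)[1]
  best <- runs[[best_i]]
  converged <- best$convergence == 0
  # The optimiser is monotone from its own start by construction; flag if the
  # final likelihood fell below the initial one (a failed run).
  loglik0 <- -negll(starts[[best_i]])
  loglik <- -best$objective
  monotone_ok <- loglik >= loglik0 - 1e-6
  if (!monotone_ok) {
    warning("log-likelihood decreased relative to the starting value; fit flagged",
            call. = FALSE)
    converged <- FALSE
  }

  u <- unpack_par(best$par, groups, control$r1, control$r2)
  params_by_group <- lapply(u$params, as_acclim_params)
  boundary_warning <- any(vapply(params_by_group, function(p) {
    min(p$td1 - lo, hi - p$td1, p$td2 - lo, hi - p$td2) < 1e-3
  }, logical(1)))
  if (boundary_warning) {
    warning("threshold estimate pinned at a bound", call. = FALSE)
  }

  se_by_group <- NULL
  vcov <- NULL
  if (converged) {
    H <- tryCatch(pracma::hessian(negll, best$par), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov) && all(is.finite(diag(vcov))) && all(diag(vcov) > 0)) {
        se <- sqrt(diag(vcov))
        se_by_group <- lapply(seq_len(k), function(i) {
          stats::setNames(se[(5 * (i - 1) + 1):(5 * i)],
                          c("y0", "v1", "v2", "td1", "td2"))
        })
        names(se_by_group) <- groups
      } else {
        vcov <- NULL
      }
    }
  }

  mu <- acclim_mean_values(params_by_group, data)
  e_marg <- data$value - mu
  blups <- acclim_blups(e_marg, data$animal_id, u$sigma_r2, u$sigma_e2)
  e_cond <- e_marg - blups[data$animal_id]
  n <- nrow(data)
  p_count <- 5L * k + 2L
  sse <- sum(e_cond^2)
  ctss <- sum((data$value - mean(data$value))^2)
  r2 <- adjusted_r2(sse, ctss, n, p_count)

  structure(list(
    params_by_group = params_by_group,
    variance = list(sigma_r2 = u$sigma_r2, sigma_e2 = u$sigma_e2),
    se_by_group = se_by_group,
    vcov = vcov,
    loglik = loglik,
    n_obs = n,
    n_params = p_count,
    adjusted_r2 = r2,
    converged = converged,
    n_iterations = best$iterations,
    boundary_warning = boundary_warning,
    blups = blups,
    groups = groups,
    data = data,
    control = control
  ), class = "acclim_fit")
}

#' @export
print.acclim_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-threshold NLMM fit: %d group(s), %d obs, logLik %.3f, adj. R2 %.3f%s\n",
              length(x$groups), x$n_obs, x$loglik, x$adjusted_r2,
              if (x$converged) "" else " [NOT CONVERGED]"))
  for (g in x$groups) {
    est <- unlist(x$params_by_group[[g]][c("y0", "v1", "v2", "td1", "td2")])
    cat(sprintf("  %s: ", g))
    cat(paste(sprintf("%s=%.*g", names(est), digits, est), collapse = ", "), "\n")
    if (!is.null(x$se_by_group)) {
      cat("      SE: ",
          paste(sprintf("%.*g", digits, x$se_by_group[[g]]), collapse = ", "), "\n")
    }
  }
  cat(sprintf("  sigma_r2 = %.*g, sigma_e2 = %.*g\n",
              digits, x$variance$sigma_r2, digits, x$variance$sigma_e2))
  invisible(x)
}

#' Adjusted R-squared
#'
#' `1 - [sse/(n - p - 1)] / [ctss/(n - 1)]`, the penalised proportion of the
#' corrected total sum of squares explained by a model with `p` parameters.
#' For mixed-model fits the package computes `sse` from conditional residuals
#' (empirical-Bayes animal intercepts included), so between-animal variation
#' captured by the random effect counts as explained.
#'
#' @param sse Sum of squared residuals (>= 0).
#' @param ctss Corrected total sum of squares (> 0).
#' @param n Number of observations; must exceed `p + 1`.
#' @param p Number of model parameters.
#' @return The adjusted R-squared (<= 1).
#' @export
adjusted_r2 <- function(sse, ctss, n, p) {
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  if (ctss <= 0) stop("ctss must be positive", call. = FALSE)
  if (sse < 0) stop("sse must be non-negative", call. = FALSE)
  1 - (sse / (n - p - 1)) / (ctss / (n - 1))
}

#' Predicted trajectories from a fitted model
#'
#' @param object An `"acclim_fit"` object.
#' @param days Days at which to predict (default: the observed fit window at
#'   0.25-d resolution).
#' @param type `"marginal"` for the population-mean curve per group,
#'   `"conditional"` to add each animal's empirical-Bayes intercept.
#' @param ... Unused.
#' @return A data frame with columns `group`, (`animal_id`,) `day`, `fit` and
#'   a logical `extrapolated` flag for days outside the fit window.
#' @export
predict.acclim_fit <- function(object, days = NULL,
                               type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  window <- attr(object$data, "window")
  if (is.null(days)) days <- seq(window[1], window[2], by = 0.25)
  extrap <- days < window[1] | days > window[2]
  if (any(extrap)) {
    warning("some prediction days lie outside the fit window (extrapolation)",
            call. = FALSE)
  }
  if (type == "marginal") {
    out <- do.call(rbind, lapply(object$groups, function(g) {
      data.frame(group = g, day = days,
                 fit = acclim_curve(object$params_by_group[[g]], days),
                 extrapolated = extrap)
    }))
    rownames(out) <- NULL
    return(out)
  }
  animals <- unique(object$data[, c("animal_id", "group")])
  out <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
    g <- animals$group[i]; a <- animals$animal_id[i]
    data.frame(group = g, animal_id = a, day = days,
               fit = acclim_curve(object$params_by_group[[g]], days) +
                 object$blups[[a]],
               extrapolated = extrap)
  }))
  rownames(out) <- NULL
  out
}

# Compact letter display from a symmetric p-value matrix: sorted by estimate,
# each maximal run of mutually non-significant groups shares a letter.
cld_from_pvalues <- function(est, pmat, alpha) {
  g <- names(est)
  ord <- order(est)
  runs <- list()
  i <- 1
  while (i <= length(g)) {
    j <- i
    while (j < length(g)) {
      ok <- all(pmat[ord[i:(j + 1)], ord[i:(j + 1)]][upper.tri(diag(j + 2 - i))] > alpha)
      if (ok) j <- j + 1 else break
    }
    runs[[length(runs) + 1]] <- ord[i:j]
    i <- if (j == length(g)) j + 1 else i + 1
  }
  # drop runs nested in another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (r in seq_along(runs)) {
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])
  }
  letters_out
}

#' Wald contrasts of acclimation parameters between groups
#'
#' For a joint multi-group fit (group-specific mean parameters, shared
#' smoothness and variance components), computes Wald z-tests for every
#' pairwise difference of each mean parameter, with two-sided p-values and a
#' compact letter display at level `alpha`.
#'
#' @param fit An `"acclim_fit"` object with at least two groups and an
#'   available covariance matrix.
#' @param alpha Significance level for the letter grouping.
#' @return A list of class `"acclim_contrasts"` with `contrasts` (data frame:
#'   `parameter`, `group1`, `group2`, `estimate1`, `estimate2`, `diff`, `se`,
#'   `z`, `p_value`) and `letters` (data frame: `parameter`, `group`,
#'   `letter`).
#' @export
compare_acclim_groups <- function(fit, alpha = NULL) {
  if (is.null(alpha)) alpha <- fit$control$alpha
  if (length(fit$groups) < 2) {
    stop("need a joint fit with at least two groups", call. = FALSE)
  }
  if (is.null(fit$vcov)) {
    stop("contrasts unavailable: covariance matrix is missing or singular",
         call. = FALSE)
  }
  par_names <- c("y0", "v1", "v2", "td1", "td2")
  groups <- fit$groups
  rows <- list()
  letter_rows <- list()
  for (p_i in seq_along(par_names)) {
    pn <- par_names[p_i]
    est <- vapply(groups, function(g) fit$params_by_group[[g]][[pn]], numeric(1))
    pmat <- matrix(1, length(groups), length(groups),
                   dimnames = list(groups, groups))
    for (a in seq_len(length(groups) - 1)) {
      for (b in seq(a + 1, length(groups))) {
        ia <- 5 * (a - 1) + p_i
        ib <- 5 * (b - 1) + p_i
        v <- fit$vcov[ia, ia] + fit$vcov[ib, ib] - 2 * fit$vcov[ia, ib]
        if (!is.finite(v) || v < 0) {
          stop("contrasts unavailable: singular information for ", pn,
               call. = FALSE)
        }
        dd <- est[a] - est[b]
        se <- sqrt(v)
        z <- if (se == 0 && dd == 0) 0 else dd / se
        pv <- 2 * stats::pnorm(-abs(z))
        pmat[a, b] <- pmat[b, a] <- pv
        rows[[length(rows) + 1]] <- data.frame(
          parameter = pn, group1 = groups[a], group2 = groups[b],
          estimate1 = est[a], estimate2 = est[b],
          diff = dd, se = se, z = z, p_value = pv)
      }
    }
    let <- cld_from_pvalues(est, pmat, alpha)
    letter_rows[[p_i]] <- data.frame(parameter = pn, group = groups,
                                     letter = unname(let[groups]))
  }
  structure(list(contrasts = do.call(rbind, rows),
                 letters = do.call(rbind, letter_rows),
                 alpha = alpha),
            class = "acclim_contrasts")
}

#' @export
print.acclim_contrasts <- function(x, digits = 4, ...) {
  cat(sprintf("Pairwise Wald contrasts (alpha = %g):\n", x$alpha))
  print(format(x$contrasts, digits = digits), row.names = FALSE)
  cat("Letter groups:\n")
  print(x$letters, row.names = FALSE)
  invisible(x)
}
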