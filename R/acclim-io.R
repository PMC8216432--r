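# CSV and configuration input/output, plus end-to-end command helpers
# (simulate, fit, summarise) usable from scripts.

trajectory_csv_columns <- c("animal_id", "group", "period", "day", "variable", "value")
trajectory_csv_variables <- c("ADFI_g_d", "ADFI_g_d_kg060", "Tcore_C", "BW_kg")

#' Read a long-format trajectory/study CSV
#'
#' Reads and validates the package's tidy CSV schema: columns `animal_id`,
#' `group`, `period` (P1/P2/P3), `day` (challenge-relative), `variable`
#' (`ADFI_g_d`, `ADFI_g_d_kg060`, `Tcore_C`, `BW_kg`) and `value`. Violations
#' are reported with the offending data line number.
#'
#' @param path Path to a CSV file (UTF-8, decimal point, comma separator).
#' @return A data frame with the schema columns.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(df) == 0) stop("schema error in ", path, ": file has no data rows",
                          call. = FALSE)
  missing_cols <- setdiff(trajectory_csv_columns, names(df))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line_of <- function(i) i + 1L  # header on line 1
  bad <- which(!df$period %in% c("P1", "P2", "P3"))
  if (length(bad)) {
    stop(sprintf("schema error in %s, line %d: invalid period '%s'",
                 path, line_of(bad[1]), df$period[bad[1]]), call. = FALSE)
  }
  bad <- which(!df$variable %in% trajectory_csv_variables)
  if (length(bad)) {
    stop(sprintf("schema error in %s, line %d: unknown variable '%s'",
                 path, line_of(bad[1]), df$variable[bad[1]]), call. = FALSE)
  }
  day <- suppressWarnings(as.numeric(df$day))
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(day) | !is.finite(value))
  if (length(bad)) {
    stop(sprintf("schema error in %s, line %d: non-numeric day or value",
                 path, line_of(bad[1])), call. = FALSE)
  }
  bad <- which(day < -3 - 1e-8 | day > 12 + 1e-8)
  if (length(bad)) {
    stop(sprintf("schema error in %s, line %d: day %g outside [-3, 12]",
                 path, line_of(bad[1]), day[bad[1]]), call. = FALSE)
  }
  df$day <- day
  df$value <- value
  df[trajectory_csv_columns]
}

#' Write a long-format trajectory/study CSV
#'
#' @param df A data frame with the schema columns of [read_trajectory_csv()]
#'   (a `"study_data"` object qualifies after adding any missing `group`
#'   column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(df, path) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(trajectory_csv_columns, names(df))
  if (length(missing_cols)) {
    stop("cannot write: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(df[trajectory_csv_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Known configuration keys and their defaults.
default_config_list <- function() {
  list(r1 = 0.25, r2 = 0.25, profile_r = FALSE,
       r_grid = "0.05,0.1,0.25,0.5,1.0",
       reltol = 1e-8, maxit = 500, multistart = 5, seed = 1,
       nodes = 9, alpha = 0.05, lattice = 0.25,
       window_lo = -1, window_hi = 10, td_lo = 0, td_hi = 10,
       n_per_group = 9, replicates = 3,
       bw_start_mean = 68.6, bw_start_sd = 4.3, bw_gain = 1.2,
       bw_noise_sd = sqrt(0.5),
       tcore_tn_ref = 38.82, tcore_tn_slope = -0.0045,
       verbose = 1)
}

#' Default run configuration
#'
#' The flat key-value configuration understood by [read_run_config()] and the
#' `cmd_*` helpers: fitter settings (`r1`, `r2`, `profile_r`, `r_grid`,
#' `reltol`, `maxit`, `multistart`, `seed`, `nodes`, `alpha`, `lattice`,
#' `window_lo`, `window_hi`, `td_lo`, `td_hi`), study-generator settings (`n_per_group`,
#' `replicates`, `bw_*`, `tcore_tn_*`) and `verbose`.
#'
#' @return A named list of defaults.
#' @export
default_run_config <- function() default_config_list()

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected; missing keys take their defaults.
#'
#' @param path Path to the configuration file.
#' @return A named list (defaults overridden by the file).
#' @export
read_run_config <- function(path) {
  defaults <- default_config_list()
  if (is.null(path)) return(defaults)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config parse error: expected 'key = value', got: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    old <- defaults[[key]]
    cfg[[key]] <- if (is.logical(old)) as.logical(val)
                  else if (is.numeric(old)) as.numeric(val)
                  else val
  }
  cfg
}

#' Write a configuration list to a flat key-value file
#'
#' @param config A named list (subset of [default_run_config()] keys).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), names(default_config_list()))
  if (length(unknown)) {
    stop("unknown configuration key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15),
                            character(1))),
             path)
  invisible(path)
}

config_to_control <- function(cfg) {
  acclim_control(
    r1 = cfg$r1, r2 = cfg$r2, profile_r = isTRUE(cfg$profile_r),
    r_grid = as.numeric(strsplit(as.character(cfg$r_grid), ",")[[1]]),
    bounds = c(cfg$td_lo, cfg$td_hi),
    reltol = cfg$reltol, maxit = cfg$maxit, multistart = cfg$multistart,
    seed = cfg$seed, nodes = cfg$nodes, alpha = cfg$alpha,
    lattice = cfg$lattice)
}

acclim_log <- function(cfg, ...) {
  if (!is.null(cfg$verbose) && cfg$verbose > 0) {
    message(sprintf(...))
  }
}

write_provenance <- function(path, cfg, extra = character()) {
  lines <- c(
    sprintf("package = heatacclim %s",
            as.character(utils::packageVersion("heatacclim"))),
    sprintf("date = %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("%s = %s", names(cfg),
            vapply(cfg, function(v) format(v, digits = 15), character(1))),
    extra)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a study and write it to disk
#'
#' Runs [simulate_study()] with the given configuration and writes the
#' long-format study CSV plus a provenance sidecar
#' (`<out>.provenance.txt`: package version, full configuration echo, seed).
#'
#' @param config A configuration list ([default_run_config()] overrides) or a
#'   path to a key-value configuration file; `NULL` for defaults.
#' @param out Output CSV path.
#' @param seed Optional seed overriding the configuration's.
#' @return The study data, invisibly.
#' @export
cmd_simulate <- function(config = NULL, out, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else utils::modifyList(default_config_list(),
                                if (is.null(config)) list() else config)
  if (!is.null(seed)) cfg$seed <- seed
  design <- study_design(n_per_group = cfg$n_per_group,
                         replicates = cfg$replicates)
  study <- simulate_study(design, seed = cfg$seed, r1 = cfg$r1, r2 = cfg$r2,
                          bw_start_mean = cfg$bw_start_mean,
                          bw_start_sd = cfg$bw_start_sd,
                          bw_gain = cfg$bw_gain, bw_noise_sd = cfg$bw_noise_sd,
                          tcore_tn_ref = cfg$tcore_tn_ref,
                          tcore_tn_slope = cfg$tcore_tn_slope)
  write_trajectory_csv(study, out)
  write_provenance(paste0(out, ".provenance.txt"), cfg,
                   extra = sprintf("presets = %s",
                                   paste(acclim_presets()$label, collapse = ";")))
  acclim_log(cfg, "wrote %d study records for %d animals to %s",
             nrow(study), length(unique(study$animal_id)), out)
  invisible(study)
}

#' Fit the acclimation model to a trajectory CSV and write reports
#'
#' Reads a trajectory CSV, selects one response variable, fits the
#' two-threshold nonlinear mixed model (one parameter set per group) and
#' writes a parameter report laid out one group per row — estimate and SE for
#' `(y0, v1, v2, td1, td2)`, the shared variance components and the
#' conditional adjusted R-squared — as both CSV (`<out_prefix>_fit.csv`) and
#' text (`<out_prefix>_fit.txt`). With two or more groups a pairwise contrast
#' table (`<out_prefix>_contrasts.csv`) is written as well.
#'
#' @param data_path Path to a trajectory CSV (see [read_trajectory_csv()]).
#' @param out_prefix Path prefix for the report files.
#' @param config Configuration list or file path (see [cmd_simulate()]).
#' @param variable Which CSV variable to model (`"ADFI_g_d_kg060"` or
#'   `"Tcore_C"`); default: whichever of the two is present.
#' @param period Optional period filter.
#' @return The `"acclim_fit"` object, invisibly.
#' @export
cmd_fit <- function(data_path, out_prefix, config = NULL, variable = NULL,
                    period = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else utils::modifyList(default_config_list(),
                                if (is.null(config)) list() else config)
  df <- read_trajectory_csv(data_path)
  if (!is.null(period)) df <- df[df$period == period, , drop = FALSE]
  fit_vars <- intersect(c("ADFI_g_d_kg060", "Tcore_C"), unique(df$variable))
  if (is.null(variable)) {
    if (length(fit_vars) != 1) {
      stop("specify `variable`: file contains ",
           paste(unique(df$variable), collapse = ", "), call. = FALSE)
    }
    variable <- fit_vars
  }
  df <- df[df$variable == variable, , drop = FALSE]
  df <- df[df$day >= cfg$window_lo - 1e-8 & df$day <= cfg$window_hi + 1e-8, ,
           drop = FALSE]
  if (nrow(df) == 0) stop("no rows for variable ", variable, call. = FALSE)
  traj <- trajectory_data(df[, c("animal_id", "group", "day", "value")],
                          variable = if (variable == "Tcore_C") "Tcore"
                                     else "ADFI_per_kg060",
                          period = if (is.null(period)) NA_character_ else period,
                          window = c(cfg$window_lo, cfg$window_hi))
  fit <- fit_acclim(traj, config_to_control(cfg))

  rep_df <- do.call(rbind, lapply(fit$groups, function(g) {
    p <- fit$params_by_group[[g]]
    se <- if (is.null(fit$se_by_group)) rep(NA_real_, 5) else fit$se_by_group[[g]]
    data.frame(group = g,
               y0 = p$y0, se_y0 = se[1], v1 = p$v1, se_v1 = se[2],
               v2 = p$v2, se_v2 = se[3], td1 = p$td1, se_td1 = se[4],
               td2 = p$td2, se_td2 = se[5],
               sigma_r2 = fit$variance$sigma_r2,
               sigma_e2 = fit$variance$sigma_e2,
               adj_r2 = fit$adjusted_r2,
               converged = fit$converged)
  }))
  utils::write.csv(rep_df, paste0(out_prefix, "_fit.csv"), row.names = FALSE,
                   quote = FALSE)
  txt <- utils::capture.output(print(fit))
  writeLines(txt, paste0(out_prefix, "_fit.txt"))
  if (length(fit$groups) >= 2 && !is.null(fit$vcov)) {
    ct <- compare_acclim_groups(fit, alpha = cfg$alpha)
    utils::write.csv(ct$contrasts, paste0(out_prefix, "_contrasts.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  acclim_log(cfg, "fit written to %s_fit.csv (logLik %.3f, adj. R2 %.3f)",
             out_prefix, fit$loglik, fit$adjusted_r2)
  invisible(fit)
}

#' Summarise interval performance of a study CSV
#'
#' Reads a study CSV, computes [interval_performance()] for every period with
#' the period's analysis pools, and writes a tidy summary CSV with columns
#' `pool`, `period`, `interval`, `adfi`, `adg`, `fg`, `n_animals`, `flagged`.
#'
#' @param study_path Path to a study CSV.
#' @param out Output CSV path.
#' @param config Configuration list or file path.
#' @return The summary data frame, invisibly.
#' @export
cmd_summarize <- function(study_path, out, config = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else utils::modifyList(default_config_list(),
                                if (is.null(config)) list() else config)
  study <- read_trajectory_csv(study_path)
  periods <- intersect(c("P1", "P2", "P3"), unique(study$period))
  summ <- do.call(rbind, lapply(periods, function(pd) {
    interval_performance(study, pd)
  }))
  utils::write.csv(summ, out, row.names = FALSE, quote = FALSE)
  acclim_log(cfg, "performance summary (%d rows) written to %s", nrow(summ), out)
  invisible(summ)
}
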