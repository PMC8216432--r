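# Built-in parameter presets for the two study variables, by period and group.
# Values are the published fitted estimates (with standard errors), variance
# components and adjusted R-squared for each fit; they drive the synthetic
# cohort generator and the parameter-recovery checks.

# One row per fitted group; variance components and adjusted R2 are shared
# within a fit (pooled P1 fit, joint P2/P3 fits, and the across-period fits of
# the repeatedly challenged HHH group).
table3_df <- function() {
  txt <- "
label            variable        period group      y0    se_y0 v1     se_v1 v2     se_v2 td1   se_td1 td2   se_td2 sigma_r2 sigma_e2 adj_r2 n_animals
ADFI/P1          ADFI_per_kg060  P1     TTH&HHH    179   14.6  -39.1  0.8   5.34   0.84  0.01  0.35   7.97  1.04   300      331      0.65   18
ADFI/P2/THT      ADFI_per_kg060  P2     THT        158   10.4  -45.6  10.9  6.50   1.14  0.27  0.26   7.26  0.86   249      245      0.67   9
ADFI/P2/HHH      ADFI_per_kg060  P2     HHH        162   14.5  -54.5  14.9  4.72   0.80  0.13  0.28   9.30  1.13   249      245      0.67   9
ADFI/P3/TTH      ADFI_per_kg060  P3     TTH        165   7.7   -36.3  7.1   11.50  2.23  1.03  0.31   5.97  0.24   295      304      0.68   9
ADFI/P3/HHH      ADFI_per_kg060  P3     HHH        159   11.4  -44.3  12.9  5.99   1.62  0.27  0.32   7.76  1.42   295      304      0.68   9
Tcore/P1         Tcore           P1     TTH&HHH    39.3  0.05  0.48   0.04  -0.30  0.02  1.46  0.13   6.30  0.20   0.038    0.036    0.87   18
Tcore/P2/THT     Tcore           P2     THT        39.2  0.12  0.36   0.07  -0.39  0.05  2.06  0.30   5.67  0.24   0.057    0.100    0.86   9
Tcore/P2/HHH     Tcore           P2     HHH        39.0  0.12  0.50   0.07  -0.34  0.03  1.43  0.20   6.42  0.38   0.057    0.100    0.86   9
Tcore/P3/TTH     Tcore           P3     TTH        39.1  0.11  0.41   0.07  -0.25  0.03  1.34  0.27   6.13  0.35   0.051    0.087    0.83   9
Tcore/P3/HHH     Tcore           P3     HHH        38.7  0.12  0.42   0.08  -0.29  0.04  1.68  0.35   6.33  0.32   0.051    0.087    0.83   9
ADFI/HHH/P1      ADFI_per_kg060  P1     HHH        177   14.8  -39.1  15.4  5.35   0.82  0.00  0.36   7.98  1.08   324      324      0.70   9
ADFI/HHH/P2      ADFI_per_kg060  P2     HHH        160   9.2   -49.8  10.2  5.49   0.78  0.20  0.21   7.99  0.77   324      324      0.70   9
ADFI/HHH/P3      ADFI_per_kg060  P3     HHH        163   6.1   -38.5  7.2   8.63   1.41  0.71  0.26   6.41  0.59   324      324      0.70   9
Tcore/HHH/P1     Tcore           P1     HHH        39.4  0.06  0.48   0.05  -0.30  0.02  1.45  0.16   6.30  0.23   0.054    0.102    0.85   9
Tcore/HHH/P2     Tcore           P2     HHH        39.1  0.07  0.44   0.05  -0.35  0.03  1.63  0.18   5.98  0.21   0.054    0.102    0.85   9
Tcore/HHH/P3     Tcore           P3     HHH        38.9  0.07  0.42   0.05  -0.27  0.02  1.50  0.19   6.25  0.23   0.054    0.102    0.85   9
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Built-in trajectory parameter presets
#'
#' Returns the table of published parameter estimates for scaled feed intake
#' (`ADFI_per_kg060`, g/d/kg^0.60) and daily-mean core temperature (`Tcore`,
#' C) by period and treatment group, including the pooled first-period
#' heat-stressed fit, the per-period single-challenge fits, and the
#' across-period fits of the repeatedly challenged (HHH) group. Standard
#' errors, variance components (`sigma_r2`, `sigma_e2`) and adjusted R-squared
#' are those of the corresponding fit.
#'
#' Labels follow `"<variable>/<period>"` for the pooled first-period fits
#' (e.g. `"ADFI/P1"`), `"<variable>/<period>/<group>"` for per-period group
#' fits (e.g. `"ADFI/P3/TTH"`), and `"<variable>/HHH/<period>"` for the
#' repeated-challenge fits (e.g. `"Tcore/HHH/P3"`).
#'
#' @return A data frame, one row per fitted group.
#' @export
acclim_presets <- function() {
  table3_df()
}

#' Retrieve a single preset
#'
#' @param label A label from [acclim_presets()], e.g. `"ADFI/P1"`,
#'   `"Tcore/P1"`, `"Tcore/HHH/P3"`.
#' @param r1,r2 Transition smoothness (d) to attach to the preset parameters
#'   (the published table reports none; the package default is 0.25 d).
#' @return A list of class `"acclim_preset"` with `label`, `variable`,
#'   `period`, `group`, `params` ([acclim_params()]), `sigma_r2`, `sigma_e2`,
#'   `adj_r2`, `n_animals` and `day_grid`.
#' @export
acclim_preset <- function(label, r1 = 0.25, r2 = 0.25) {
  tab <- table3_df()
  row <- tab[tab$label == label, ]
  if (nrow(row) != 1) {
    stop("unknown preset label: ", label,
         " (see acclim_presets() for the available labels)", call. = FALSE)
  }
  structure(list(
    label = label,
    variable = row$variable,
    period = row$period,
    group = row$group,
    params = acclim_params(y0 = row$y0, v1 = row$v1, v2 = row$v2,
                           td1 = row$td1, td2 = row$td2, r1 = r1, r2 = r2),
    se = c(y0 = row$se_y0, v1 = row$se_v1, v2 = row$se_v2,
           td1 = row$se_td1, td2 = row$se_td2),
    sigma_r2 = row$sigma_r2,
    sigma_e2 = row$sigma_e2,
    adj_r2 = row$adj_r2,
    n_animals = row$n_animals,
    day_grid = -1:10
  ), class = "acclim_preset")
}

#' @export
print.acclim_preset <- function(x, ...) {
  cat(sprintf("Preset %s (%s, %s, group %s): n = %d\n",
              x$label, x$variable, x$period, x$group, x$n_animals))
  print(x$params)
  cat(sprintf("  sigma_r2 = %g, sigma_e2 = %g, adj. R2 = %g\n",
              x$sigma_r2, x$sigma_e2, x$adj_r2))
  invisible(x)
}
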