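# Shared fixtures for the test suite: preset shortcuts and a central
# finite-difference oracle for gradients.

tcore_p1 <- function(r1 = 0.25, r2 = 0.25) acclim_preset("Tcore/P1", r1, r2)
adfi_p1 <- function(r1 = 0.25, r2 = 0.25) acclim_preset("ADFI/P1", r1, r2)

# central finite differences of the mean curve w.r.t. (y0, v1, v2, td1, td2)
fd_gradient <- function(params, d, h = 1e-5) {
  pn <- c("y0", "v1", "v2", "td1", "td2")
  sapply(pn, function(nm) {
    up <- params; up[[nm]] <- up[[nm]] + h
    dn <- params; dn[[nm]] <- dn[[nm]] - h
    (acclim_curve(up, d) - acclim_curve(dn, d)) / (2 * h)
  })
}

# quick single-group dataset from a preset
sim_preset <- function(label, n = 18, seed = 1, days = -1:10,
                       r1 = 0.25, r2 = 0.25) {
  simulate_trajectories(acclim_preset(label, r1, r2), n_animals = n,
                        days = days, seed = seed)
}

# fast control for tests that do not probe optimiser robustness
fast_control <- function(...) acclim_control(multistart = 2, ...)
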