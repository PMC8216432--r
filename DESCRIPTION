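Package: heatacclim
Title: Biphasic Heat-Acclimation Trajectory Modelling for Growing Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model feed-intake and core body-temperature trajectories of
    growing pigs during multi-day heat challenges with a smooth two-threshold
    broken-line mean function fitted as a nonlinear mixed model (per-animal random
    intercept, marginal maximum likelihood). Includes the closed-form
    compound-symmetry marginal likelihood with an adaptive Gauss-Hermite quadrature
    cross-check, Wald group contrasts with compact letter displays, conditional
    adjusted R-squared, a synthetic cohort generator reproducing a 5-group by
    3-period challenge design, interval growth-performance summaries (ADFI, ADG,
    feed:gain), metabolic body-weight scaling, and tidy CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
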