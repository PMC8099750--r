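Package: taulanding
Title: Per-Track Analysis of Optic-Flow Guided Landing Deceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how flying insects decelerate when landing on
    a surface using the relative rate of optical expansion (r = V/y) and
    time-to-contact (tau = y/V). Provides trajectory simulators for the
    constant-r, constant-tau-dot and hybrid (bout-wise constant-r with a
    constant-tau-dot set-point schedule) guidance laws, Savitzky-Golay based
    kinematic state estimation, an automatic detector of constant-r segments
    governed by a sensitivity factor f, mixed-model estimation of the
    time-to-contact rate from the log-log relation between set points and
    distance, gamma fits to the set-point distribution, and speed comparisons
    between the hybrid strategy and its pure reference strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    emmeans,
    tibble,
    dplyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    fitdistrplus,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
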