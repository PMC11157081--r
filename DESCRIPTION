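Package: hypojump
Title: Neuromechanics of Targeted Countermovement Jumps in Simulated Hypogravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vertically targeted countermovement jumps
    performed before, during, and after exposure to simulated hypogravity
    (body-weight support). Segments jumps into lift, aerial, and landing phases
    from vertical ground reaction force, computes lift and landing impulses,
    jump height and target error; detects triceps-surae preactivation onset
    before landing with a cumulative-integration elbow method and
    low-activation exclusion gates; estimates muscle-tendon-junction geometry,
    medial gastrocnemius length and velocity with rolling-shutter timing
    correction, and spindle group-Ia afferent firing rates; and compares
    conditions with a wavelet-domain functional paired t-test and a gated
    paired t / Wilcoxon battery with Hedges g_av effect sizes. Includes a
    synthetic trial generator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
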