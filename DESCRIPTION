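Package: ednadrift
Title: Decay Kinetics and Lagrangian Dispersal of Marine Environmental DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how the functional form of environmental DNA
    (eDNA) decay shapes the dispersal of eDNA plumes in coastal seas. The
    package generates synthetic tidal surface-current and temperature fields
    and tank-experiment style eDNA concentration series, fits first-order and
    two-component exponential decay models with replicate-level offsets and
    compares them by AIC, classifies decay patterns (exponential, biphasic,
    delayed), runs a 2-D Lagrangian particle tracker (fourth-order
    Runge-Kutta advection, random-walk horizontal diffusion, binomial
    survival) under four decay scenarios, computes event-based dispersal
    metrics (alive counts, centre of mass, mean displacement, dispersion,
    convex-hull area, density), and decomposes the variance of standardized
    metrics over scenario, metric and time with Type III tests and partial
    eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    minpack.lm,
    car,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
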