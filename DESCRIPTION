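Package: dplskin
Title: Dual-Phase-Lag Thermoelastic Simulation of Skin Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-analytic simulator for one-dimensional thermoelastic skin
    tissue under the dual-phase-lag (DPL) heat-conduction law with Pennes-type
    blood perfusion. The outer surface is loaded by thermal shock, ramp-type,
    or harmonic heating; temperature-increment, strain, displacement and
    stress profiles are obtained from the closed-form Laplace-domain solution
    of the coupled conduction/motion system and inverted numerically by the
    Riemann-sum (Tzou) method. Includes an independent finite-difference
    time-domain solver for cross-validation, parameter-sweep drivers,
    wavefront (jump) detection, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
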