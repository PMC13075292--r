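Package: mrbscan
Title: Simulation and Quantitation for Scanning Contactless-Conductivity
    Detection of Moving Reaction Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electrophoresis-titration quantitation with a scanning
    capacitively coupled contactless conductivity detector (sC4D). Provides a
    forward model of the conductivity profile around a moving reaction boundary
    (linear, error-function, and 1-D Nernst-Planck descriptions), a
    sliding-window detector response that turns spatial profiles into scan
    traces, the signal-processing pipeline that localizes the boundary in each
    scan (baseline subtraction, moving-average filtering, derivative and trough
    localization), velocity estimation and log-linear calibration with limit of
    detection, relative standard deviation and spike-recovery arithmetic, a
    seeded synthetic-experiment generator, and a command-line interface binding
    the stages into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
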