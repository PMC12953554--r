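Package: edukinetics
Title: Cell-Cycle Kinetics from Cumulative EdU Labeling Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of growth fraction, S-phase duration (Ts) and total
    cell-cycle duration (Tc) from cumulative thymidine-analog (EdU) labeling
    time courses, using a three-segment breakpoint fit of the labeling index
    curve or the classical linear-rise model, with field-level bootstrap
    confidence intervals and condition comparisons. Includes an agent-based
    simulator of asynchronous cycling populations and phenomenological
    lagged-rise curve generators for parameter-recovery studies, marker
    labeling-index statistics (Ki67, phospho-histone H3, mitotic figures)
    with two-tailed Student's t-tests, and 2^-ddCt relative qPCR
    quantification with technical-replicate collapsing and housekeeping
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
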