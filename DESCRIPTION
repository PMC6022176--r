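Package: efsgait
Title: Temporal Gait Parameters from Electrostatic Field Sensing Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for non-contact gait measurement
    by electrostatic field sensing (EFS). Provides a physics-based forward
    model of the induced-current signal a charged walking body drives through
    a nearby electrode, a companion simulator of the force-sensitive-resistor
    (FSR) insole reference channel, foot-event detectors for both channels
    (initial contact and foot-off), per-cycle temporal gait parameters
    (cycle, stance and swing durations, cadence, stance/swing ratios), and
    agreement statistics (event-error summaries, gait-cycle accuracy, Pearson
    correlation with qualitative grading, and ICC(2,1) test-retest
    reliability). All tabular results are tibbles; plotting uses ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
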