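Package: spfgait
Title: Sensory Processing and Gait Event Detection for an Instrumented
    Prosthetic Foot
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing stack for a prosthetic foot instrumented with
    an array of optoelectronic pressure sensors (tactels) and an inertial
    measurement unit. Converts tactel voltages to forces through a quartic
    calibration polynomial, estimates the vertical ground reaction force and
    the longitudinal center of pressure, detects heel-strike and toe-off
    events with two independent real-time detectors (a pressure threshold
    rule and an IMU finite-state machine), and benchmarks event timing and
    waveform agreement against a force-plate reference. Includes a seeded
    synthetic gait simulator with ground-truth events for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
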