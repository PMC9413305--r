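Package: instep
Title: Foot Trajectory Reconstruction for Instep Kicks from a Single
    Six-Axis IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the three-dimensional foot trajectory of a football
    instep kick from a single foot-mounted six-axis inertial measurement unit
    (accelerometer plus gyroscope) and extracts kick-quality metrics. The
    pipeline covers two's-complement decoding of raw sensor words, sphere-model
    accelerometer calibration, quaternion attitude propagation from angular
    rate, static-window gravity compensation with tilt leveling, and gated
    trapezoidal double integration with zero-velocity updates. Kick metrics
    (path length, maximum foot speed, backswing apex height) and agreement
    statistics against a reference trajectory (RMSE, Bland-Altman limits of
    agreement) are provided, together with a synthetic instep-kick simulator
    that inverts an analytic ground-truth trajectory into realistic raw IMU
    streams for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
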