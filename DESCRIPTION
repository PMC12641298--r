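Package: margsense
Title: Orientation Estimation and Concurrent Validation for Wearable MARG Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates body-segment orientations from consumer-grade MARG
    (magnetic, angular-rate, gravity) sensor streams and scores them against a
    reference optical-motion-capture orientation series. Provides retrospective
    magnetometer hard/soft-iron ellipsoid calibration and static gyroscope bias
    removal, the Madgwick gradient-descent sensor-fusion filter, quaternion,
    direction-cosine-matrix and Euler XYZ conversions, handedness and temporal
    alignment (cropping, resampling, cross-correlation synchronization, static
    heading correction, baselining), and RMSE-based movement-quality accuracy
    scoring with z-score outlier exclusion. A synthetic-data module
    forward-models both the sensor and the reference system from a known
    ground-truth trajectory so the whole pipeline is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
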