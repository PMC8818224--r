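Package: accelcat
Title: Behaviour Categorisation from Collar-Mounted Tri-Axial Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, calibrates, and classifies collar-mounted tri-axial
    accelerometer recordings of large-felid behaviour. Provides a ground-truthed
    gait and posture signal simulator with configurable data-logger profiles
    (sampling rate, clip bound, amplitude resolution), rail-reference mounting
    calibration, derivation of the fourteen standard per-sample predictor
    channels (raw, static, and dynamic acceleration per axis, VeDBA, VeSBA,
    Anim.stat, pitch, roll), an ethogram label model with fine, medium, and
    coarse behaviour resolutions, random-forest behaviour classifiers with
    early stopping and depth tuning, and evaluation tools including confusion
    matrices, per-behaviour accuracy, and chi-squared device comparison.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
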