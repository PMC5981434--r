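Package: migranight
Title: Sleep-Time Wearable Biosignal Analysis for Early Migraine Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting impending migraine attacks from
    wrist-worn sensor recordings of sleep. Reads and writes the Empatica E4
    CSV export dialect (accelerometer, blood volume pulse, electrodermal
    activity, heart rate, skin temperature, inter-beat intervals), estimates
    the nightly sleep interval from actigraphy, extracts a 110-feature
    nightly vector including time-domain heart-rate-variability indices,
    expands the small imbalanced night set into pairwise night-comparison
    observations, and classifies with regularized linear or quadratic
    discriminant analysis after noise-injected sequential forward feature
    selection. Includes a seeded synthetic-cohort generator and the personal
    and leave-one-subject-out evaluation protocol with night-level mode
    aggregation and balanced accuracy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
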