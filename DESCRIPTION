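Package: seatpose
Title: Driver Posture Recognition from Seat Pressure Maps with Reduced Sensor Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring a seated driver's posture from body pressure
    distributions measured by backrest and seat-pan sensor mats. Provides mat
    segmentation into subareas and regional areas, a 200-candidate collection of
    pressure features (centers of pressure, contact area proportions, pressure
    ratios, area statistics) computed relative to a task-initial standard
    posture, kinematics-based posture class labelling with an intra-/inter-motion
    redundancy filter, per-body-part classifiers with out-of-bag permutation
    feature importance and leave-one-subject-out cross-validation, and an
    evaluation harness for reduced-resolution sensor layouts built by recursive
    uniform sampling with inverse-distance-weighting reconstruction. Includes a
    synthetic body-pressure-distribution generator so the full pipeline can be
    exercised without instrumented-seat recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    randomForest,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart,
    jsonlite,
    optparse
Config/testthat/edition: 3
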