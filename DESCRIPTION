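Package: surgact
Title: Unsupervised Surgical Activity Recognition from Video and Sensor
    Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for unsupervised recognition of surgical activities in
    simulator trajectories that combine video frames with time-aligned
    categorical sensor channels. The package implements self-supervised
    representation learning on a remaining-surgery-progress pretext task
    (a compact convolutional encoder feeding a gated recurrent decoder and
    a small regression head, trained with mean absolute error), kernel
    change-point analysis (PELT) of internal network activations to mine
    event-locked features, construction of a latched "diagnosis ended"
    observable from decoder gate activations, and decoding of activity
    sequences with an explicit-duration hidden semi-Markov model with
    negative-binomial dwell times and per-channel categorical emissions.
    A synthetic trajectory generator emulating a hysteroscopic myomectomy
    simulator provides fully reproducible benchmarks, and evaluation
    utilities report per-activity intersection-over-union scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
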