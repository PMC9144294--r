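Package: gaitspeed
Title: Semi-Supervised Variational Autoencoders for IMU-Based Gait Speed
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates instantaneous bipedal motion speed (walking and
    running, km/h) from raw windows of wearable inertial measurement unit
    (IMU) signals recorded at the thigh, shin and foot.  Implements a
    semi-supervised variational autoencoder whose decoder is a single dense
    layer of weighted sine waves (SVAE-Sine), together with an
    LSTM/transposed-convolution decoder variant, the surrounding pipeline
    (20-column recording I/O with unit conversion and sensor saturation
    handling, resampling to an isochronal 512 Hz grid, 2-second windowing
    with centre-sample labels, rotation and relative-noise augmentation,
    early-stopped training, uniform random hyper-parameter search,
    subject-wise leave-one-out cross-validation, sensor-placement studies),
    and a synthetic quasi-periodic gait-signal generator so the whole
    pipeline is testable without the real dataset.  The network layers and
    their gradients are implemented natively in vectorised R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
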