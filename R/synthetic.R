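# Synthetic quasi-periodic IMU gait recordings with ground-truth speed.
#
# The generator is phenomenological: each channel is a sum of harmonics of
# the instantaneous step frequency, whose frequency and amplitude both grow
# with speed, plus gravity (accelerometer), measurement noise, sensor
# saturation and irregular ~400 Hz sampling.  It reproduces the statistical
# structure a speed estimator exploits, not biomechanically accurate
# waveforms.

#' Per-subject gait model parameters
#'
#' Draws one subject's signal model: a piecewise-linear step-frequency law
#' `f(v) = a + b * v` (Hz, with distinct walking and running coefficients
#' and a regime-switch speed around 8 km/h), per-placement amplitude laws
#' that grow linearly with speed (largest and most speed-sensitive at the
#' foot), harmonic weights, per-channel phase offsets, a gravity direction,
#' measurement noise levels and the irregular-sampling parameters.
#'
#' @param seed integer seed identifying the subject.
#' @param rate nominal sampling rate in Hz (default 400).
#' @param jitter relative standard deviation of the sample interval.
#' @return an object of class `gait_model_params`.
#' @export
gait_model_params <- function(seed = 1L, rate = 400, jitter = 0.1) {
  set.seed(seed)
  rpos <- function(mu, sd) max(mu + stats::rnorm(1L, 0, sd), mu / 4)
  n_harm <- 3L
  amp_laws <- list(
    foot  = list(acc_base = rpos(4, 0.6),  acc_slope = rpos(2.8, 0.3),
                 gyr_base = rpos(50, 8),   gyr_slope = rpos(70, 8)),
    shin  = list(acc_base = rpos(3, 0.5),  acc_slope = rpos(1.2, 0.15),
                 gyr_base = rpos(40, 6),   gyr_slope = rpos(35, 5)),
    thigh = list(acc_base = rpos(2, 0.4),  acc_slope = rpos(0.4, 0.06),
                 gyr_base = rpos(30, 5),   gyr_slope = rpos(12, 2)))
  harm <- list()
  for (p in SENSOR_PLACEMENTS) for (kind in c("acc", "gyr")) {
    w <- matrix(0, 3L, n_harm)   # axis x harmonic relative weights
    ph <- matrix(stats::runif(3L * n_harm, 0, 2 * pi), 3L, n_harm)
    # inter-subject spread of harmonic content: ~±15% overall, ~±20% per
    # harmonic, in line with amplitude variability of healthy adult gait
    for (ax in 1:3)
      w[ax, ] <- c(1, 0.5, 0.25) * stats::runif(n_harm, 0.8, 1.2) *
        stats::runif(1L, 0.85, 1.15)
    harm[[paste(p, kind, sep = "_")]] <- list(w = w, phase = ph)
  }
  gdir <- stats::rnorm(3L); gdir <- gdir / sqrt(sum(gdir^2))
  structure(list(
    walk_a = rpos(1.2, 0.08), walk_b = rpos(0.15, 0.015),
    run_a = rpos(2.0, 0.1), run_b = rpos(0.05, 0.008),
    switch_speed = rpos(8, 0.7),
    amp_laws = amp_laws, harm = harm, n_harm = n_harm,
    gravity = 9.81 * gdir,
    noise_acc = 0.3, noise_gyr = 3,
    rate = rate, jitter = jitter, seed = as.integer(seed)),
    class = "gait_model_params")
}

#' Instantaneous step frequency of a subject at given speeds
#'
#' @param params a [gait_model_params()].
#' @param v speed(s) in km/h.
#' @return step frequency in Hz, strictly increasing in `v` within each
#'   regime.
#' @export
step_frequency <- function(params, v) {
  walk <- params$walk_a + params$walk_b * v
  run <- params$run_a + params$run_b * v
  ifelse(v < params$switch_speed, walk, pmax(run, walk))
}

#' Construct a speed profile
#'
#' @param speed numeric trace of speeds (km/h, >= 0).
#' @param rate internal sampling rate of the trace in Hz.
#' @return an object of class `speed_profile` with fields `speed`, `time`,
#'   `rate`, `duration`.
#' @export
speed_profile <- function(speed, rate = 50) {
  stopifnot(all(speed >= 0))
  structure(list(speed = as.numeric(speed),
                 time = (seq_along(speed) - 1L) / rate,
                 rate = rate,
                 duration = (length(speed) - 1L) / rate),
            class = "speed_profile")
}

#' Generate a random piecewise-smooth speed profile
#'
#' Alternates dwell segments (steady speed drawn from the walking and
#' running ranges, roughly 0-25 km/h) with linear ramps whose slope is
#' bounded by `ramp_limit`.
#'
#' @param duration profile duration in seconds.
#' @param seed optional integer seed.
#' @param rate internal trace rate in Hz (default 50).
#' @param max_speed upper speed bound in km/h.
#' @param ramp_limit maximum |dv/dt| in (km/h)/s.
#' @return a [speed_profile()] of `duration * rate + 1` samples.
#' @export
generate_speed_profile <- function(duration, seed = NULL, rate = 50,
                                   max_speed = 25, ramp_limit = 2) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  knots_t <- 0
  knots_v <- stats::runif(1L, 0, max_speed)
  t_cur <- 0
  while (t_cur < duration) {
    dwell <- stats::runif(1L, 3, 8)
    knots_t <- c(knots_t, t_cur + dwell)
    knots_v <- c(knots_v, knots_v[length(knots_v)])
    v_next <- stats::runif(1L, 0, max_speed)
    ramp <- abs(v_next - knots_v[length(knots_v)]) /
      stats::runif(1L, 0.5 * ramp_limit, ramp_limit)
    knots_t <- c(knots_t, t_cur + dwell + max(ramp, 0.25))
    knots_v <- c(knots_v, v_next)
    t_cur <- t_cur + dwell + max(ramp, 0.25)
  }
  tt <- seq(0, duration, by = 1 / rate)
  sp <- stats::approx(knots_t, knots_v, xout = tt, rule = 2)$y
  speed_profile(pmax(sp, 0), rate)
}

#' Constant-speed profile
#' @param v speed in km/h; @param duration seconds; @param rate trace Hz.
#' @export
constant_speed_profile <- function(v, duration, rate = 50) {
  speed_profile(rep(v, round(duration * rate) + 1L), rate)
}

profile_at <- function(profile, times) {
  stats::approx(profile$time, profile$speed, xout = times, rule = 2)$y
}

#' Clip values at a sensor's saturation limit
#'
#' @param x numeric values in physical units.
#' @param limit positive saturation limit; values are clipped to
#'   `[-limit, limit]`.
#' @export
apply_saturation <- function(x, limit) {
  stopifnot(limit > 0)
  pmin(pmax(x, -limit), limit)
}

#' Synthesize one subject's raw 20-column recording
#'
#' Generates jittered ~400 Hz timestamps, evaluates the speed profile at
#' them, accumulates the gait phase from the instantaneous step frequency,
#' builds every accelerometer/gyroscope channel as a sum of harmonics with
#' speed-dependent amplitude plus gravity (accelerometer) and white noise,
#' clips at the +-80 m/s^2 / +-2000 deg/s sensor limits, and inverse-applies
#' the unit-conversion multipliers to store integer raw counts.
#'
#' @param params a [gait_model_params()].
#' @param profile a [speed_profile()].
#' @param seed optional integer seed for noise and sampling jitter.
#' @param subject_id subject identifier (default derived from the params
#'   seed).
#' @return a [raw_recording()] in raw counts (`units_converted = FALSE`).
#' @export
synthesize_recording <- function(params, profile, seed = NULL,
                                 subject_id = NULL) {
  stopifnot(inherits(params, "gait_model_params"),
            inherits(profile, "speed_profile"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(subject_id)) subject_id <- paste0("S", params$seed)
  n_approx <- ceiling(profile$duration * params$rate * 1.2) + 10L
  dt <- (1 / params$rate) *
    pmax(1 + stats::rnorm(n_approx, 0, params$jitter), 0.3)
  times <- cumsum(c(0, dt))
  times <- times[times <= profile$duration]
  n <- length(times)
  v <- profile_at(profile, times)
  fstep <- step_frequency(params, v)
  phase <- cumsum(c(0, fstep[-1L] * diff(times)))  # cycles
  mat <- matrix(0, n, 20L)
  for (pi in seq_along(SENSOR_PLACEMENTS)) {
    p <- SENSOR_PLACEMENTS[pi]
    law <- params$amp_laws[[p]]
    amp_acc <- law$acc_base + law$acc_slope * v
    amp_gyr <- law$gyr_base + law$gyr_slope * v
    ha <- params$harm[[paste(p, "acc", sep = "_")]]
    hg <- params$harm[[paste(p, "gyr", sep = "_")]]
    for (ax in 1:3) {
      acc <- params$gravity[ax] +
        stats::rnorm(n, 0, params$noise_acc)
      gyr <- stats::rnorm(n, 0, params$noise_gyr)
      for (m in seq_len(params$n_harm)) {
        s_acc <- sin(2 * pi * m * phase + ha$phase[ax, m])
        s_gyr <- sin(2 * pi * m * phase + hg$phase[ax, m])
        acc <- acc + amp_acc * ha$w[ax, m] * s_acc
        gyr <- gyr + amp_gyr * hg$w[ax, m] * s_gyr
      }
      mat[, accel_cols(p)[ax]] <- apply_saturation(acc, ACCEL_LIMIT)
      mat[, gyro_cols(p)[ax]] <- apply_saturation(gyr, GYRO_LIMIT)
    }
  }
  # inverse unit conversion to integer raw counts, clipped so that the
  # converted values respect the sensor limits exactly
  acc_max <- floor(ACCEL_LIMIT / ACCEL_SCALE)
  gyr_max <- floor(GYRO_LIMIT / GYRO_SCALE)
  mat[, 1:9] <- pmin(pmax(round(mat[, 1:9] / ACCEL_SCALE), -acc_max), acc_max)
  mat[, 10:18] <- pmin(pmax(round(mat[, 10:18] / GYRO_SCALE), -gyr_max), gyr_max)
  mat[, 19L] <- v
  mat[, 20L] <- times
  raw_recording(mat, subject_id, units_converted = FALSE)
}

#' Write a raw recording to a delimited text file
#'
#' Writes the 20-column raw-count matrix without header.  Sensor counts are
#' written as integers; the speed and time columns are written with 17
#' significant digits so that reading the file back with
#' [load_recording()] reproduces the recording bit-exactly.
#'
#' @param rec a [raw_recording()] in raw counts.
#' @param path output path (`.csv`).
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$units_converted)
    stop("write_recording() expects raw counts (units_converted = FALSE)")
  dt <- data.table::as.data.table(rec$mat)
  for (j in 1:18) data.table::set(dt, j = j, value = as.integer(dt[[j]]))
  for (j in 19:20)
    data.table::set(dt, j = j, value = sprintf("%.17g", dt[[j]]))
  data.table::fwrite(dt, path, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a multi-subject synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param duration recording duration per subject in seconds.
#' @param seed root seed; per-subject parameter/profile/noise seeds are
#'   derived deterministically from it.
#' @param dir optional directory; when given, each subject's recording is
#'   written to `<dir>/S<k>.csv`.
#' @return named list of [raw_recording()]s; written file paths, if any,
#'   are attached as attribute `"paths"`.
#' @export
simulate_cohort <- function(n_subjects, duration = 300, seed = 1L,
                            dir = NULL) {
  recs <- list()
  paths <- character(0)
  for (k in seq_len(n_subjects)) {
    params <- gait_model_params(seed = seed + 17L * k)
    profile <- generate_speed_profile(duration, seed = seed + 17L * k + 7L)
    rec <- synthesize_recording(params, profile, seed = seed + 17L * k + 13L,
                                subject_id = paste0("S", k))
    recs[[paste0("S", k)]] <- rec
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, paste0("S", k, ".csv"))
      write_recording(rec, p)
      paths <- c(paths, p)
    }
  }
  if (length(paths)) attr(recs, "paths") <- paths
  recs
}
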