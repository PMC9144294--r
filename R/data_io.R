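# Reading, validating and unit-converting 20-column IMU recordings.
#
# Column layout (1-based): 1:9 accelerometer (1:3 thigh, 4:6 shin, 7:9 foot,
# raw counts, x 0.0024 -> m/s^2), 10:18 gyroscope (10:12 thigh, 13:15 shin,
# 16:18 foot, raw counts, x 0.061 -> deg/s), 19 reference speed (km/h),
# 20 time (s).

#' Sensor placements in canonical order
#' @export
SENSOR_PLACEMENTS <- c("thigh", "shin", "foot")

#' Physical constants of the recording format
#'
#' `ACCEL_SCALE` and `GYRO_SCALE` convert raw sensor counts to m/s^2 and
#' deg/s respectively; `ACCEL_LIMIT` and `GYRO_LIMIT` are the saturation
#' limits of the sensor in physical units.
#' @export
ACCEL_SCALE <- 0.0024

#' @rdname ACCEL_SCALE
#' @export
GYRO_SCALE <- 0.061

#' @rdname ACCEL_SCALE
#' @export
ACCEL_LIMIT <- 80

#' @rdname ACCEL_SCALE
#' @export
GYRO_LIMIT <- 2000

# 1-based raw-matrix column blocks per placement
accel_cols <- function(placement) {
  switch(placement, thigh = 1:3, shin = 4:6, foot = 7:9,
         stop("unknown placement: ", placement))
}

gyro_cols <- function(placement) {
  switch(placement, thigh = 10:12, shin = 13:15, foot = 16:18,
         stop("unknown placement: ", placement))
}

channel_names <- function(placements) {
  ax <- c("x", "y", "z")
  c(unlist(lapply(placements, function(p) paste(p, "acc", ax, sep = "_"))),
    unlist(lapply(placements, function(p) paste(p, "gyr", ax, sep = "_"))))
}

#' Construct a raw recording object
#'
#' A `raw_recording` holds one subject's sample matrix in the published
#' 20-column layout together with a flag recording whether the raw counts
#' have been converted to physical units.
#'
#' @param mat numeric matrix with exactly 20 columns.
#' @param subject_id character scalar identifying the subject.
#' @param units_converted logical; `TRUE` once [convert_units()] has been
#'   applied (accelerometer columns in m/s^2, gyroscope columns in deg/s).
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(mat, subject_id, units_converted = FALSE) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("recording matrix must be numeric")
  if (ncol(mat) != 20L)
    stop("recording must have exactly 20 columns, got ", ncol(mat))
  if (anyNA(mat)) stop("recording contains missing values")
  tm <- mat[, 20L]
  if (is.unsorted(tm)) stop("time column must be non-decreasing")
  rec <- structure(
    list(mat = unname(mat), subject_id = as.character(subject_id),
         units_converted = isTRUE(units_converted)),
    class = "raw_recording")
  if (rec$units_converted) check_saturation(rec)
  rec
}

check_saturation <- function(rec) {
  # one raw count of slack absorbs integer rounding of the stored counts
  a <- rec$mat[, 1:9]
  g <- rec$mat[, 10:18]
  if (max(abs(a)) > ACCEL_LIMIT + ACCEL_SCALE)
    stop("accelerometer values exceed the ±80 m/s^2 sensor limit")
  if (max(abs(g)) > GYRO_LIMIT + GYRO_SCALE)
    stop("gyroscope values exceed the ±2000 deg/s sensor limit")
  invisible(rec)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s: %d samples, %.1f s, units %s\n",
              x$subject_id, nrow(x$mat),
              diff(range(x$mat[, 20L])),
              if (x$units_converted) "physical" else "raw counts"))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `raw_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$mat)

#' Load a recording from disk
#'
#' Reads one subject's array in the published 20-column layout.  Delimited
#' text (`.csv`, `.txt`, `.tsv`; no header) and serialized R arrays (`.rds`)
#' are supported; the format is auto-detected from the file extension.
#'
#' @param path path to the recording file.
#' @param subject_id subject identifier attached to the recording; defaults
#'   to the file name without extension.
#' @return a `raw_recording` with `units_converted = FALSE`.
#' @export
load_recording <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  mat <- switch(
    ext,
    rds = as.matrix(readRDS(path)),
    csv = , txt = , tsv = {
      dt <- data.table::fread(path, header = FALSE, colClasses = "numeric",
                              showProgress = FALSE)
      as.matrix(dt)
    },
    stop("unsupported recording format: .", ext))
  if (!is.numeric(mat)) stop("recording did not parse to a numeric matrix")
  raw_recording(mat, subject_id, units_converted = FALSE)
}

#' Convert raw sensor counts to physical units
#'
#' Scales the nine accelerometer columns by 0.0024 (to m/s^2) and the nine
#' gyroscope columns by 0.061 (to deg/s).  Speed and time columns are left
#' untouched.  Conversion may be applied only once.
#'
#' @param rec a `raw_recording` with `units_converted = FALSE`.
#' @return the converted `raw_recording` (`units_converted = TRUE`).
#' @export
convert_units <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$units_converted)
    stop("recording is already unit-converted")
  mat <- rec$mat
  mat[, 1:9]   <- mat[, 1:9]   * ACCEL_SCALE
  mat[, 10:18] <- mat[, 10:18] * GYRO_SCALE
  raw_recording(mat, rec$subject_id, units_converted = TRUE)
}

#' Define a sensor selection
#'
#' @param placements character vector, non-empty subset of
#'   `c("thigh", "shin", "foot")` (order and duplicates ignored; the
#'   canonical thigh-shin-foot order is always used).
#' @return an object of class `sensor_selection`.
#' @export
sensor_selection <- function(placements) {
  if (length(placements) == 0L)
    stop("sensor selection must contain at least one placement")
  placements <- unique(as.character(placements))
  bad <- setdiff(placements, SENSOR_PLACEMENTS)
  if (length(bad))
    stop("unknown placement(s): ", paste(bad, collapse = ", "))
  structure(list(placements = SENSOR_PLACEMENTS[SENSOR_PLACEMENTS %in% placements]),
            class = "sensor_selection")
}

as_sensor_selection <- function(x) {
  if (inherits(x, "sensor_selection")) x else sensor_selection(x)
}

#' Extract the channel matrix for a sensor selection
#'
#' Returns the 6 x |placements| channels (3 accelerometer + 3 gyroscope axes
#' per placement) as a channels x samples matrix in physical units.  Channel
#' order is deterministic: accelerometer channels first, then gyroscope
#' channels, placements in thigh-shin-foot order within each block; row
#' names carry `<placement>_<acc|gyr>_<x|y|z>` labels.
#'
#' @param rec a unit-converted `raw_recording`.
#' @param sel a `sensor_selection` (or character vector of placements).
#' @return numeric matrix, `6 * length(placements)` rows.
#' @export
select_channels <- function(rec, sel) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!rec$units_converted)
    stop("select_channels() requires a unit-converted recording")
  sel <- as_sensor_selection(sel)
  p <- sel$placements
  cols <- c(unlist(lapply(p, accel_cols)), unlist(lapply(p, gyro_cols)))
  m <- t(rec$mat[, cols, drop = FALSE])
  rownames(m) <- channel_names(p)
  m
}

#' Reference speed and time traces of a recording
#' @param rec a `raw_recording`.
#' @return numeric vector (km/h for `recording_speed`, s for `recording_time`).
#' @export
recording_speed <- function(rec) rec$mat[, 19L]

#' @rdname recording_speed
#' @export
recording_time <- function(rec) rec$mat[, 20L]
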