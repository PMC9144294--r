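# Training-set augmentation: small per-sensor rotations and relative noise.
# Labels are never altered; augmentation is meant for training folds only.

#' Augmentation configuration
#'
#' @param rotation_angle_std standard deviation of the rotation angle in
#'   degrees (default 2.5).
#' @param relative_noise_std standard deviation of the multiplicative
#'   Gaussian noise as a fraction of the observed value (default 0.01,
#'   i.e. 1%).
#' @param copies_per_window augmented copies generated per original window.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(rotation_angle_std = 2.5,
                           relative_noise_std = 0.01,
                           copies_per_window = 1L,
                           seed = NULL) {
  stopifnot(rotation_angle_std >= 0, relative_noise_std >= 0,
            copies_per_window >= 0)
  structure(list(rotation_angle_std = rotation_angle_std,
                 relative_noise_std = relative_noise_std,
                 copies_per_window = as.integer(copies_per_window),
                 seed = seed),
            class = "augment_config")
}

#' Draw a small random 3-D rotation
#'
#' The rotation angle is drawn from N(0, `angle_std` degrees) and the axis
#' uniformly on the unit sphere; the operator is assembled with the
#' Rodrigues formula, so it is orthonormal with determinant +1 by
#' construction.
#'
#' @param angle_std angle standard deviation in degrees (>= 0).
#' @return a 3x3 rotation matrix; the drawn angle (radians, signed) is
#'   attached as attribute `"angle"`.
#' @export
random_rotation <- function(angle_std) {
  stopifnot(angle_std >= 0)
  theta <- stats::rnorm(1L, 0, angle_std * pi / 180)
  u <- stats::rnorm(3L)
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  attr(R, "angle") <- theta
  R
}

#' Rotate one sensor's channels within a window
#'
#' Applies the same rotation to the 3-axis accelerometer triad and the
#' 3-axis gyroscope triad of the chosen placement, constant over the whole
#' window; all other channels are untouched.  This emulates a slightly
#' different physical mounting of that sensor.
#'
#' @param window channels x T matrix with `<placement>_<acc|gyr>_<xyz>`
#'   row names (as produced by [select_channels()]/[make_windows()]).
#' @param placement one of `"thigh"`, `"shin"`, `"foot"`; must be present
#'   in the window.
#' @param R a 3x3 rotation matrix.
#' @return the rotated window.
#' @export
rotate_sensor <- function(window, placement, R) {
  rn <- rownames(window)
  if (is.null(rn)) stop("window must carry channel row names")
  ax <- c("x", "y", "z")
  acc <- paste(placement, "acc", ax, sep = "_")
  gyr <- paste(placement, "gyr", ax, sep = "_")
  if (!all(c(acc, gyr) %in% rn))
    stop("placement '", placement, "' not present in window")
  window[acc, ] <- R %*% window[acc, , drop = FALSE]
  window[gyr, ] <- R %*% window[gyr, , drop = FALSE]
  window
}

#' Add relative Gaussian noise to a window
#'
#' Each sample x is replaced by x * (1 + eta) with eta ~ N(0, `rel_std`),
#' independently per element; zero samples therefore stay zero.
#'
#' @param window numeric matrix or array.
#' @param rel_std relative noise standard deviation (>= 0).
#' @return the perturbed window.
#' @export
add_relative_noise <- function(window, rel_std) {
  stopifnot(rel_std >= 0)
  if (rel_std == 0) return(window)
  window * (1 + stats::rnorm(length(window), 0, rel_std))
}

#' Augment a window set
#'
#' Returns the original windows plus `copies_per_window` augmented copies
#' of each: one uniformly chosen sensor is rotated by a small random
#' rotation, then relative Gaussian noise is added to all channels.
#' Labels and subject ids are copied unchanged.
#'
#' @param ws a [window_set()] whose channels carry placement row names.
#' @param cfg an [augment_config()].
#' @return the augmented `window_set`.
#' @export
augment_batch <- function(ws, cfg = augment_config()) {
  stopifnot(inherits(ws, "window_set"), inherits(cfg, "augment_config"))
  if (n_windows(ws) == 0L) stop("cannot augment an empty window set")
  if (cfg$copies_per_window == 0L) return(ws)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rn <- dimnames(ws$X)[[1L]]
  placements <- SENSOR_PLACEMENTS[SENSOR_PLACEMENTS %in%
                                    unique(sub("_.*", "", rn))]
  N <- n_windows(ws)
  copies <- vector("list", cfg$copies_per_window)
  for (cp in seq_len(cfg$copies_per_window)) {
    Xa <- ws$X
    for (k in seq_len(N)) {
      w <- Xa[, , k]
      rownames(w) <- rn
      p <- placements[sample.int(length(placements), 1L)]
      w <- rotate_sensor(w, p, random_rotation(cfg$rotation_angle_std))
      w <- add_relative_noise(w, cfg$relative_noise_std)
      Xa[, , k] <- w
    }
    copies[[cp]] <- window_set(Xa, ws$y, ws$subject, rate = ws$rate)
  }
  ws_concat(c(list(ws), copies))
}
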