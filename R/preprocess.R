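# Resampling to an isochronal grid and fixed-length windowing.

#' Resample a recording onto an isochronal grid
#'
#' Interpolates the selected IMU channels and the reference speed trace of a
#' unit-converted recording onto a uniform grid (default 512 Hz) spanning
#' the recorded time range.  Interpolation is piecewise linear per channel,
#' which cannot overshoot on saturated plateaus.  Samples sharing a
#' timestamp are averaged before interpolation.
#'
#' @param rec a unit-converted [raw_recording()].
#' @param rate target sampling rate in Hz (default 512).
#' @param sel sensor selection; default all three placements (18 channels).
#' @return an object of class `uniform_recording`: list with `signal`
#'   (channels x n matrix, physical units), `speed` (km/h, length n),
#'   `time` (s), `rate`, `subject_id`.
#' @export
resample_uniform <- function(rec, rate = 512, sel = SENSOR_PLACEMENTS) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!rec$units_converted)
    stop("resample_uniform() requires a unit-converted recording")
  tm <- recording_time(rec)
  if (length(tm) < 2L) stop("need at least 2 samples to resample")
  ch <- select_channels(rec, sel)
  sp <- recording_speed(rec)
  if (anyDuplicated(tm)) {
    grp <- match(tm, unique(tm))
    ch <- t(apply(ch, 1L, function(v) tapply(v, grp, mean)))
    sp <- as.numeric(tapply(sp, grp, mean))
    tm <- unique(tm)
  }
  if (any(diff(tm) <= 0))
    stop("time not strictly increasing after de-duplication")
  if (length(tm) < 2L) stop("need at least 2 distinct timestamps")
  grid <- seq(tm[1L], tm[length(tm)], by = 1 / rate)
  sig <- matrix(0, nrow(ch), length(grid), dimnames = list(rownames(ch), NULL))
  for (c_i in seq_len(nrow(ch)))
    sig[c_i, ] <- stats::approx(tm, ch[c_i, ], xout = grid)$y
  speed <- stats::approx(tm, sp, xout = grid)$y
  structure(list(signal = sig, speed = speed, time = grid, rate = rate,
                 subject_id = rec$subject_id),
            class = "uniform_recording")
}

#' @export
print.uniform_recording <- function(x, ...) {
  cat(sprintf("<uniform_recording> subject %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$rate))
  invisible(x)
}

#' Restrict a uniform recording to a sensor subset
#'
#' @param urec a `uniform_recording` containing the requested placements.
#' @param sel sensor selection.
#' @return a `uniform_recording` with only the selected channels.
#' @export
uniform_select <- function(urec, sel) {
  sel <- as_sensor_selection(sel)
  want <- channel_names(sel$placements)
  missing <- setdiff(want, rownames(urec$signal))
  if (length(missing))
    stop("recording lacks channels: ", paste(missing, collapse = ", "))
  urec$signal <- urec$signal[want, , drop = FALSE]
  urec
}

#' Construct a window set
#'
#' Container for a stack of fixed-length windows.  `X` is stored as a
#' channels x T x N array (the layout used by the network code); `y` holds
#' the centre-sample speed labels in km/h.
#'
#' @param X numeric array C x T x N.
#' @param y numeric length-N label vector (km/h).
#' @param subject character length-N subject ids.
#' @param rate sampling rate of the windows in Hz.
#' @return an object of class `window_set`.
#' @export
window_set <- function(X, y, subject, rate = 512) {
  stopifnot(length(dim(X)) == 3L, dim(X)[3L] == length(y),
            length(subject) == length(y))
  structure(list(X = X, y = as.numeric(y), subject = as.character(subject),
                 h = dim(X)[2L] %/% 2L, rate = rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<window_set> %d windows of %d channels x %d samples (%d subject%s)\n",
              d[3L], d[1L], d[2L], length(unique(x$subject)),
              if (length(unique(x$subject)) == 1L) "" else "s"))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @export
n_windows <- function(ws) dim(ws$X)[3L]

#' Cut a uniform recording into fixed-length labelled windows
#'
#' Cuts `window_s`-second windows (T = rate * window_s samples) with the
#' given stride; the label of each window is the speed at its middle
#' element, i.e. at 0-based offset T/2 from the window start.  A recording
#' shorter than one window yields an empty window set with a warning.
#'
#' @param urec a `uniform_recording`.
#' @param window_s window length in seconds (default 2).
#' @param stride hop between window starts, in samples; default T/2
#'   (50% overlap).  Use `stride = T` for non-overlapping evaluation
#'   windows.
#' @return a [window_set()].
#' @export
make_windows <- function(urec, window_s = 2, stride = NULL) {
  stopifnot(inherits(urec, "uniform_recording"))
  T_len <- as.integer(round(urec$rate * window_s))
  if (is.null(stride)) stride <- T_len %/% 2L
  stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  C <- nrow(urec$signal)
  n <- ncol(urec$signal)
  if (n < T_len) {
    warning(sprintf("recording too short for a %d-sample window (n = %d)",
                    T_len, n))
    return(window_set(array(0, c(C, T_len, 0L)), numeric(0), character(0),
                      rate = urec$rate))
  }
  N <- (n - T_len) %/% stride + 1L
  starts <- seq.int(1L, by = stride, length.out = N)
  X <- array(0, c(C, T_len, N))
  for (k in seq_len(N))
    X[, , k] <- urec$signal[, starts[k] + 0:(T_len - 1L)]
  dimnames(X) <- list(rownames(urec$signal), NULL, NULL)
  y <- urec$speed[starts + T_len %/% 2L]
  window_set(X, y, rep(urec$subject_id, N), rate = urec$rate)
}

#' Subset a window set by window index
#' @param ws a `window_set`.
#' @param idx integer or logical index over windows.
#' @export
ws_subset <- function(ws, idx) {
  window_set(ws$X[, , idx, drop = FALSE], ws$y[idx], ws$subject[idx],
             rate = ws$rate)
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical channel/time dimensions,
#'   or a single list of them.
#' @export
ws_concat <- function(...) {
  wss <- list(...)
  if (length(wss) == 1L && !inherits(wss[[1L]], "window_set"))
    wss <- wss[[1L]]
  d1 <- dim(wss[[1L]]$X)[1:2]
  for (w in wss) stopifnot(all(dim(w$X)[1:2] == d1))
  Ns <- vapply(wss, n_windows, integer(1))
  X <- array(0, c(d1, sum(Ns)))
  dimnames(X) <- dimnames(wss[[1L]]$X)
  at <- 0L
  for (w in wss) {
    if (n_windows(w) > 0L) X[, , at + seq_len(n_windows(w))] <- w$X
    at <- at + n_windows(w)
  }
  window_set(X, unlist(lapply(wss, `[[`, "y")),
             unlist(lapply(wss, `[[`, "subject")), rate = wss[[1L]]$rate)
}
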