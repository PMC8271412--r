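#' Resample a recording onto a uniform grid
#'
#' Smartphone accelerometers deliver samples at a non-uniform rate of around
#' 10 Hz; all downstream processing assumes a uniform grid. Each axis is
#' linearly interpolated onto `t = 0, 1/rate, 2/rate, ...` (time re-based to
#' the first sample); the grid never extends past the last sample, so no
#' extrapolation occurs.
#'
#' @param rec An [accel_recording()] tibble (possibly non-uniform).
#' @param rate Target sampling rate in Hz (default 10).
#' @return A uniform `accel_recording` at `rate` Hz.
#' @export
resample_uniform <- function(rec, rate = 10) {
  if (nrow(rec) < 2L) stop("need at least 2 samples to resample", call. = FALSE)
  stopifnot(rate > 0)
  t0 <- rec$t[1]
  span <- rec$t[nrow(rec)] - t0
  grid <- seq(0, by = 1 / rate, length.out = floor(span * rate + 1e-9) + 1)
  src <- rec$t - t0
  out <- accel_recording(
    t = grid,
    ax = stats::approx(src, rec$ax, xout = grid, ties = "ordered")$y,
    ay = stats::approx(src, rec$ay, xout = grid, ties = "ordered")$y,
    az = stats::approx(src, rec$az, xout = grid, ties = "ordered")$y,
    subject_id = attr(rec, "subject_id"),
    start_datetime = attr(rec, "start_datetime")
  )
  attr(out, "rate") <- rate
  out
}

#' Median filter a uniform recording
#'
#' Replaces each axis value by the median of all samples within
#' `window / 2` seconds on either side, to suppress high-frequency sensor
#' noise and brief non-gravitational accelerations before angles are
#' computed. At the edges the window truncates (shrinks) rather than pad,
#' so no data are fabricated.
#'
#' @param rec Uniformly sampled recording.
#' @param window Full window length in seconds (default 60).
#' @return Filtered recording of the same shape.
#' @export
median_filter <- function(rec, window = 60) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  if (!is_uniform(rec$t)) stop("median_filter requires uniform sampling", call. = FALSE)
  n <- nrow(rec)
  if (n < 3L) return(rec)
  dt <- rec$t[2] - rec$t[1]
  half <- floor(window / 2 / dt + 1e-9)
  out <- rec
  for (col in c("ax", "ay", "az")) {
    out[[col]] <- truncated_runmed(rec[[col]], half)
  }
  out
}

# Sliding median over index window [i - half, i + half], truncated at both
# ends. Interior points come from stats::runmed (identical full windows);
# the first/last `half` points are recomputed with the shrinking window.
truncated_runmed <- function(x, half) {
  n <- length(x)
  if (half < 1L) return(x)
  k <- 2L * half + 1L
  if (k >= n) {
    return(vapply(seq_len(n), function(i) {
      stats::median(x[max(1L, i - half):min(n, i + half)])
    }, numeric(1)))
  }
  med <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  edge <- seq_len(half)
  med[edge] <- vapply(edge, function(i) stats::median(x[1:(i + half)]), numeric(1))
  tail_edge <- (n - half + 1L):n
  med[tail_edge] <- vapply(tail_edge, function(i) stats::median(x[(i - half):n]),
                           numeric(1))
  med
}

#' Planar gravity angle of an acceleration vector
#'
#' The workhorse orientation formula: for an in-plane vector `(x, z)` and a
#' sign argument `c`, returns `(180 / pi) * acos(x / sqrt(x^2 + z^2)) *
#' sign(c)` in degrees, wrapped to (-180, 180]. With the sternum-worn body
#' frame, the sleep angle uses `(X, Z)` with `c = Z` (0 deg = pure left,
#' 90 = supine, +-180 = right, -90 = prone) and the stand angle uses
#' `(Y, Z)` with `c = Z` (+-90 = laying, +-180 = standing, 0 = headstand).
#' `sign(0)` is defined as +1, placing boundary cases on the positive side.
#'
#' @param x,z In-plane acceleration components (any common unit; the result
#'   is scale invariant).
#' @param c Sign argument (typically `z`).
#' @return Angle in degrees in (-180, 180]; `NA` where `(x, z) == (0, 0)`.
#' @examples
#' raw_angle(0, 1, 1)   # pure supine: 90
#' raw_angle(1, 0, 0)   # pure left: 0
#' raw_angle(0, -1, -1) # pure prone: -90
#' @export
raw_angle <- function(x, z, c) {
  norm <- sqrt(x^2 + z^2)
  sgn <- ifelse(c >= 0, 1, -1)
  ang <- ifelse(norm > 0, 180 / pi * acos(pmin(pmax(x / norm, -1), 1)) * sgn,
                NA_real_)
  wrap_angle(ang)
}

#' Estimate per-recording calibration offsets
#'
#' The additive offset `theta_initial` corrects for anatomy and device
#' placement. It is determined from the first `window` seconds of the
#' recording, during which the wearer is assumed to lie supine: the offset
#' maps the circular mean of the raw angle over that window to 90 degrees.
#' Sleep and stand angles get independent offsets. Recordings shorter than
#' the window fall back to zero offsets with a warning.
#'
#' @param series Tibble with `t`, `sleep_angle`, `stand_angle` (raw,
#'   uncalibrated).
#' @param window Calibration window in seconds (default 600).
#' @return List with `theta_sleep`, `theta_stand` (degrees) and `window`.
#' @export
calibrate_angles <- function(series, window = 600) {
  if (recording_duration(series) < window) {
    warning("recording shorter than calibration window; using zero offsets",
            call. = FALSE)
    return(list(theta_sleep = 0, theta_stand = 0, window = window))
  }
  head_idx <- series$t <= series$t[1] + window
  list(
    theta_sleep = wrap_angle(90 - circ_mean(series$sleep_angle[head_idx])),
    theta_stand = wrap_angle(90 - circ_mean(series$stand_angle[head_idx])),
    window = window
  )
}

#' Compute calibrated sleep and stand angles
#'
#' Takes a resampled, median-filtered recording and produces the angle
#' series: sleep angle from the X--Z plane, stand angle from the Y--Z
#' plane, both with sign argument Z, plus the per-recording calibration
#' offsets (estimated from the supine start unless supplied). Samples whose
#' in-plane vector is exactly zero are flagged invalid.
#'
#' @param rec Uniform, filtered [accel_recording()].
#' @param calibration Optional list with `theta_sleep`/`theta_stand`
#'   (degrees) to override automatic calibration.
#' @param auto_calibrate Estimate offsets from the first
#'   `calibration_window` seconds (default `TRUE`; `FALSE` means zero
#'   offsets unless `calibration` is given).
#' @param calibration_window Seconds of assumed-supine data used for
#'   calibration (default 600).
#' @return Tibble `t, sleep_angle, stand_angle, valid` of class
#'   `angle_series`, with the calibration stored in
#'   `attr(, "calibration")` and the sampling rate in `attr(, "rate")`.
#' @export
compute_angles <- function(rec, calibration = NULL, auto_calibrate = TRUE,
                           calibration_window = 600) {
  sleep_raw <- raw_angle(rec$ax, rec$az, rec$az)
  stand_raw <- raw_angle(rec$ay, rec$az, rec$az)
  series <- tibble::tibble(t = rec$t, sleep_angle = sleep_raw,
                           stand_angle = stand_raw)
  if (is.null(calibration)) {
    calibration <- if (auto_calibrate) {
      calibrate_angles(series, window = calibration_window)
    } else {
      list(theta_sleep = 0, theta_stand = 0, window = calibration_window)
    }
  }
  series$sleep_angle <- wrap_angle(series$sleep_angle + calibration$theta_sleep)
  series$stand_angle <- wrap_angle(series$stand_angle + calibration$theta_stand)
  series$valid <- !is.na(series$sleep_angle) & !is.na(series$stand_angle)
  attr(series, "calibration") <- calibration
  attr(series, "rate") <- attr(rec, "rate") %||%
    (if (nrow(rec) > 1) 1 / (rec$t[2] - rec$t[1]) else NA_real_)
  class(series) <- c("angle_series", class(series))
  series
}
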