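# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

# per-grid-angle counts by explicit double loop over the circular distance
naive_window_counts <- function(angles, half_window = 7.5) {
  grid <- -180:179
  vapply(grid, function(th) {
    d <- (angles - th + 180) %% 360 - 180
    d[d == -180] <- 180
    sum(abs(d) <= half_window)
  }, numeric(1))
}

naive_pct <- function(angles, half_window = 7.5) {
  100 * naive_window_counts(angles, half_window) / length(angles)
}

# truncated-window sliding median, one median() call per sample
naive_sliding_median <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# circular mean through complex arithmetic (independent of circ_mean)
naive_circ_mean <- function(deg) {
  z <- mean(exp(1i * deg * pi / 180))
  a <- Arg(z) * 180 / pi
  if (a <= -180) a <- a + 360
  a
}

# local ODI by double loop + the same clamp/mask/smooth contract
naive_local_odi <- function(event_angles, sample_angles, dt,
                            half_window = 7.5, floor_min = 10, radius = 2) {
  ns <- naive_window_counts(sample_angles, half_window)
  ne <- naive_window_counts(event_angles, half_window)
  hours <- ns * dt / 3600
  raw <- ifelse(ns > 0, ne / pmax(hours, floor_min / 60), NA_real_)
  sm <- raw
  n <- length(raw)
  for (i in seq_len(n)) {
    if (is.na(raw[i])) next
    idx <- ((i - 1 + (-radius:radius)) %% n) + 1
    sm[i] <- mean(raw[idx], na.rm = TRUE)
  }
  list(raw = raw, smoothed = sm)
}

# uniform angle series builder (10 Hz, all laying) for profile tests
make_angle_series <- function(sleep, stand = 90, dt = 0.1) {
  n <- length(sleep)
  s <- tibble::tibble(
    t = seq(0, by = dt, length.out = n),
    sleep_angle = sleep,
    stand_angle = rep_len(stand, n),
    valid = TRUE
  )
  attr(s, "rate") <- 1 / dt
  class(s) <- c("angle_series", class(s))
  somnpose::classify_position(s)
}

# trapezoidal SpO2 dip injected into a constant-baseline series
make_dip_series <- function(duration = 3600, baseline = 97, onset = 600,
                            depth = 4, descent = 45, plateau = 10,
                            recovery = 35) {
  tt <- 0:duration
  s <- rep(baseline, length(tt))
  tau <- tt - onset
  dip <- pmin(pmax(tau / descent, 0), 1) -
    pmin(pmax((tau - descent - plateau) / recovery, 0), 1)
  tibble::tibble(t = tt, spo2 = s - depth * dip)
}

# greedy nadir-time matching between planted and detected events
match_events <- function(planted_nadir, detected_nadir, tol = 30) {
  used <- rep(FALSE, length(detected_nadir))
  hits <- 0L
  for (p in planted_nadir) {
    d <- abs(detected_nadir - p)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      hits <- hits + 1L
    }
  }
  list(tp = hits, fn = length(planted_nadir) - hits,
       fp = sum(!used))
}
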