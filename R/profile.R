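#' Analysis configuration for angle-resolved profiles
#'
#' Bundles the tunable constants of the positional analysis. The per-degree
#' grid runs from -180 to 179 (360 points; +180 aliases -180), each grid
#' angle collects samples within `half_window` degrees (so a 15-degree
#' window by default), the local ODI denominator is floored at
#' `min_position_minutes` of occupancy and the event/position ratio
#' denominator at `min_position_percent`, and the local ODI is smoothed
#' with a circular moving average of `smooth_radius` neighbours on each
#' side.
#'
#' @param half_window Angular half-window in degrees (default 7.5).
#' @param min_position_minutes Denominator floor for the local ODI, minutes
#'   (default 10).
#' @param min_position_percent Denominator floor for the ratio, percent
#'   (default 1).
#' @param smooth_radius Neighbours on each side in the local-ODI smoother
#'   (default 2, i.e. a 5-point window).
#' @param samples_per_hour Angle samples per hour of occupancy; `NULL`
#'   (default) derives it from the series sampling rate (36,000 at 10 Hz).
#' @param smooth Apply the local-ODI smoothing (default `TRUE`).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(half_window = 7.5, min_position_minutes = 10,
                            min_position_percent = 1, smooth_radius = 2,
                            samples_per_hour = NULL, smooth = TRUE) {
  stopifnot(half_window > 0, min_position_minutes >= 0,
            min_position_percent >= 0, smooth_radius >= 0)
  structure(list(half_window = half_window,
                 min_position_minutes = min_position_minutes,
                 min_position_percent = min_position_percent,
                 smooth_radius = smooth_radius,
                 samples_per_hour = samples_per_hour,
                 smooth = smooth),
            class = "analysis_config")
}

profile_grid <- function() -180:179

# Number of angles within `half_window` degrees (circular, inclusive) of
# each integer grid angle. An angle a covers exactly the integer grid
# angles in [ceiling(a - w), floor(a + w)]; those circular intervals are
# accumulated with a difference array over a doubled grid, so the result
# matches the naive double loop exactly while staying O(n + grid).
angle_window_counts <- function(angles, half_window = 7.5) {
  angles <- angles[!is.na(angles)]
  stopifnot(half_window > 0, half_window < 180)
  counts <- numeric(360L)
  if (length(angles) == 0L) return(counts)
  lo <- ceiling(angles - half_window)
  len <- floor(angles + half_window) - lo + 1
  s_idx <- ((lo + 180) %% 360) + 1 # 1..360 on the doubled grid
  d <- numeric(721L)
  add <- tabulate(s_idx, nbins = 721L)
  sub <- tabulate(s_idx + len, nbins = 721L)
  covered <- cumsum(add - sub)[1:720]
  counts <- covered[1:360] + covered[361:720]
  counts
}

laying_angles <- function(series) {
  if (!"position" %in% names(series)) series <- classify_position(series)
  series$sleep_angle[series$position %in% laying_levels]
}

#' Percentage of laying time per sleep angle
#'
#' For each integer grid angle theta, the percentage of laying samples
#' whose sleep angle lies within the angular window around theta. Because
#' the windows overlap (each sample sits in 15 one-degree windows at the
#' default half-window of 7.5), the profile sums to 1500 over the grid,
#' not 100.
#'
#' @param series Classified `angle_series`; only laying samples count.
#' @param cfg An [analysis_config()].
#' @return Tibble `theta, n_samples, pct_position`.
#' @export
pct_position <- function(series, cfg = analysis_config()) {
  ang <- laying_angles(series)
  n <- length(ang)
  if (n == 0L) stop("no laying samples in series", call. = FALSE)
  counts <- angle_window_counts(ang, cfg$half_window)
  tibble::tibble(theta = profile_grid(), n_samples = counts,
                 pct_position = 100 * counts / n)
}

#' Assign each desaturation event its sleep angle
#'
#' The event angle is the circular mean (or median) of the sleep-angle
#' samples recorded between the event's baseline and end times. Events
#' overlapping no angle samples are dropped with a warning.
#'
#' @param events Event tibble from [detect_desaturations()].
#' @param series Classified `angle_series`.
#' @param statistic `"mean"` (default) or `"median"` -- the circular
#'   statistic summarising the within-event angles.
#' @return `events` with an `assigned_angle` column added.
#' @export
assign_event_angles <- function(events, series,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fn <- if (statistic == "mean") circ_mean else circ_median
  events$assigned_angle <- purrr::map2_dbl(
    events$t_baseline, events$t_end,
    function(a, b) {
      idx <- series$t >= a & series$t <= b
      fn(series$sleep_angle[idx])
    }
  )
  dropped <- is.na(events$assigned_angle)
  if (any(dropped)) {
    warning(sum(dropped), " event(s) overlap no angle samples; dropped",
            call. = FALSE)
    events <- events[!dropped, ]
  }
  events
}

#' Percentage of desaturation events per sleep angle
#'
#' For each grid angle, the percentage of events whose assigned angle lies
#' within the angular window. Zero events yield an all-zero profile with a
#' warning.
#'
#' @param events Events with `assigned_angle` (see [assign_event_angles()]).
#' @param cfg An [analysis_config()].
#' @return Tibble `theta, n_events, pct_de`.
#' @export
pct_de <- function(events, cfg = analysis_config()) {
  n <- nrow(events)
  if (n == 0L) {
    warning("no desaturation events: %DE profile is all zero", call. = FALSE)
    return(tibble::tibble(theta = profile_grid(), n_events = 0,
                          pct_de = 0))
  }
  counts <- angle_window_counts(events$assigned_angle, cfg$half_window)
  tibble::tibble(theta = profile_grid(), n_events = counts,
                 pct_de = 100 * counts / n)
}

#' Local oxygen desaturation index per sleep angle
#'
#' The ODI restricted to each angular window: events assigned to the
#' window divided by the hours spent in it (samples / `samples_per_hour`).
#' Denominators are floored at `min_position_minutes` to avoid artifacts
#' from briefly visited angles; grid angles with zero occupancy are masked
#' (`NA`, `valid_odi = FALSE`). The clamped profile is then smoothed with a
#' circular moving average over `smooth_radius` neighbours on each side,
#' masked cells excluded from the average.
#'
#' @param events Events with `assigned_angle`.
#' @param series Classified `angle_series`.
#' @param cfg An [analysis_config()].
#' @return Tibble `theta, hours, local_odi_raw, local_odi, valid_odi`
#'   where `local_odi_raw` is unsmoothed (but clamped) and `local_odi`
#'   smoothed.
#' @export
local_odi <- function(events, series, cfg = analysis_config()) {
  pos <- pct_position(series, cfg)
  ev <- pct_de(events, cfg)
  sph <- cfg$samples_per_hour %||% (3600 / series_dt(series))
  hours <- pos$n_samples / sph
  valid <- pos$n_samples > 0
  floor_h <- cfg$min_position_minutes / 60
  raw <- ifelse(valid, ev$n_events / pmax(hours, floor_h), NA_real_)
  smoothed <- if (isTRUE(cfg$smooth)) {
    circular_mean_smooth(raw, cfg$smooth_radius)
  } else {
    raw
  }
  tibble::tibble(theta = profile_grid(), hours = hours,
                 local_odi_raw = raw, local_odi = smoothed,
                 valid_odi = valid)
}

# circular moving average ignoring NA cells; NA cells stay NA
circular_mean_smooth <- function(x, radius) {
  if (radius < 1) return(x)
  n <- length(x)
  out <- x
  for (i in which(!is.na(x))) {
    idx <- ((i - 1 + (-radius:radius)) %% n) + 1
    out[i] <- mean(x[idx], na.rm = TRUE)
  }
  out
}

#' Event/position ratio per sleep angle
#'
#' The per-angle over-representation of desaturation events: percentage of
#' events divided by percentage of time, with the denominator floored at
#' `min_position_percent`. Values above 2 flag angles where events are at
#' least twice over-represented relative to occupancy. Angles with zero
#' occupancy are masked.
#'
#' @param de Tibble from [pct_de()].
#' @param pos Tibble from [pct_position()].
#' @param cfg An [analysis_config()].
#' @return Tibble `theta, ratio, valid_ratio`.
#' @export
ratio_de_position <- function(de, pos, cfg = analysis_config()) {
  stopifnot(identical(de$theta, pos$theta))
  valid <- pos$pct_position > 0
  ratio <- ifelse(valid,
                  de$pct_de / pmax(pos$pct_position, cfg$min_position_percent),
                  NA_real_)
  tibble::tibble(theta = de$theta, ratio = ratio, valid_ratio = valid)
}

#' Full angle-resolved positional profile
#'
#' Convenience wrapper combining [pct_position()], [pct_de()],
#' [local_odi()] and [ratio_de_position()] on one night. With `events =
#' NULL` only the occupancy profile is computed (with a warning), e.g.
#' when no oximetry was recorded.
#'
#' @param series Classified `angle_series`.
#' @param events Events with `assigned_angle`, or `NULL`.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `positional_profile` with columns `theta,
#'   n_samples, pct_position, hours, n_events, pct_de, local_odi_raw,
#'   local_odi, ratio, valid_odi, valid_ratio`.
#' @export
positional_profile <- function(series, events = NULL,
                               cfg = analysis_config()) {
  pos <- pct_position(series, cfg)
  if (is.null(events)) {
    warning("no SpO2 events supplied: profile limited to %position",
            call. = FALSE)
    out <- dplyr::mutate(pos, hours = NA_real_, n_events = NA_real_,
                         pct_de = NA_real_, local_odi_raw = NA_real_,
                         local_odi = NA_real_, ratio = NA_real_,
                         valid_odi = FALSE, valid_ratio = FALSE)
    class(out) <- c("positional_profile", class(out))
    return(out)
  }
  de <- pct_de(events, cfg)
  odi <- local_odi(events, series, cfg)
  rat <- ratio_de_position(de, pos, cfg)
  out <- pos |>
    dplyr::mutate(hours = odi$hours, n_events = de$n_events,
                  pct_de = de$pct_de, local_odi_raw = odi$local_odi_raw,
                  local_odi = odi$local_odi, ratio = rat$ratio,
                  valid_odi = odi$valid_odi, valid_ratio = rat$valid_ratio)
  class(out) <- c("positional_profile", class(out))
  out
}

#' Stack per-subject profiles into cohort heatmap matrices
#'
#' @param profiles Named list of `positional_profile` tibbles (names are
#'   subject ids).
#' @return List of four subject-by-angle matrices (`pct_de`,
#'   `pct_position`, `ratio`, `local_odi`), 360 columns each, masked cells
#'   as `NA`.
#' @export
profile_matrices <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- paste0("subject_", seq_along(profiles))
  }
  pick <- function(col) {
    m <- do.call(rbind, lapply(profiles, function(p) p[[col]]))
    dimnames(m) <- list(names(profiles), profile_grid())
    m
  }
  list(pct_de = pick("pct_de"), pct_position = pick("pct_position"),
       ratio = pick("ratio"), local_odi = pick("local_odi"))
}

#' Write cohort heatmap matrices as CSV (masked cells as empty fields)
#'
#' @param profiles Named list of profiles (see [profile_matrices()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_profile_matrices <- function(profiles, dir) {
  mats <- profile_matrices(profiles)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(mats), function(nm) {
    df <- tibble::as_tibble(mats[[nm]], rownames = "subject")
    p <- file.path(dir, paste0("heatmap_", nm, ".csv"))
    readr::write_csv(df, p, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Read a heatmap matrix CSV back (empty fields become NA masks)
#'
#' @param path CSV written by [write_profile_matrices()].
#' @return Subject-by-angle numeric matrix.
#' @export
read_profile_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$subject
  m
}
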