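#' Build an accelerometry recording tibble
#'
#' A recording is a tibble with columns `t` (seconds since acquisition
#' start), and `ax`, `ay`, `az` (acceleration in g units along the body
#' frame: X right-to-left, Y toe-to-head, Z front-to-back, for a device worn
#' flat over the sternum). Metadata travel as attributes so the tibble keeps
#' working with dplyr verbs.
#'
#' @param t Numeric vector of timestamps in seconds, non-negative.
#' @param ax,ay,az Numeric acceleration in g.
#' @param subject_id Optional subject identifier.
#' @param start_datetime Optional `POSIXct` acquisition start.
#' @return A tibble of class `accel_recording`, sorted by `t`, duplicate
#'   timestamps collapsed (last wins).
#' @export
accel_recording <- function(t, ax, ay, az, subject_id = NA_character_,
                            start_datetime = NULL) {
  stopifnot(length(t) == length(ax), length(t) == length(ay),
            length(t) == length(az))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("timestamps must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az))) {
    stop("acceleration values must be finite", call. = FALSE)
  }
  rec <- tibble::tibble(t = t, ax = ax, ay = ay, az = az)
  rec <- dplyr::arrange(rec, .data$t)
  dup <- duplicated(rec$t, fromLast = TRUE)
  if (any(dup)) rec <- rec[!dup, ]
  attr(rec, "subject_id") <- subject_id
  attr(rec, "start_datetime") <- start_datetime
  class(rec) <- c("accel_recording", class(rec))
  rec
}

#' Read a raw accelerometry CSV
#'
#' Expects a comma-separated file with header `t,ax,ay,az`; `t` in seconds,
#' accelerations in g (or m/s^2 with `units = "ms2"`, divided by 9.80665 on
#' read -- the angle computation is scale invariant, so the unit only
#' matters for thresholds applied to magnitudes).
#'
#' @param path Path to the CSV file.
#' @param units `"g"` (default) or `"ms2"`.
#' @param subject_id Optional subject identifier stored on the result.
#' @return An [accel_recording()] tibble.
#' @export
read_accel <- function(path, units = c("g", "ms2"), subject_id = NA_character_) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_strict_csv(path, c("t", "ax", "ay", "az"))
  scale <- if (units == "ms2") 1 / 9.80665 else 1
  accel_recording(df$t, df$ax * scale, df$ay * scale, df$az * scale,
                  subject_id = subject_id)
}

# Strict numeric CSV reader: errors name the first offending line (header is
# line 1). Hand-rolled on top of readLines because readr silently coerces bad
# cells to NA, and the io contract requires a line-numbered parse error.
read_strict_csv <- function(path, cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  if (!identical(header, cols)) {
    stop("expected header '", paste(cols, collapse = ","), "' in ", path,
         call. = FALSE)
  }
  if (length(lines) == 1L) stop("no data rows in ", path, call. = FALSE)
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  n_fields <- lengths(body)
  if (any(n_fields != length(cols))) {
    bad <- which(n_fields != length(cols))[1] + 1L
    stop("malformed row at line ", bad, " of ", path, call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(body)))),
                ncol = length(cols), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1] + 1L
    stop("non-numeric value at line ", bad, " of ", path, call. = FALSE)
  }
  colnames(mat) <- cols
  tibble::as_tibble(mat)
}

#' Write a recording (or any t/ax/ay/az tibble) as CSV
#'
#' @param rec Recording tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel <- function(rec, path) {
  readr::write_csv(rec[, c("t", "ax", "ay", "az")], path)
  invisible(path)
}

#' Recording duration in seconds
#'
#' @param rec Recording or any tibble with a `t` column.
#' @return `last t - first t`, in seconds (0 for a single sample).
#' @export
recording_duration <- function(rec) {
  if (nrow(rec) == 0L) return(0)
  max(rec$t) - min(rec$t)
}

#' Is a recording long enough to analyse?
#'
#' Acquisitions shorter than two minutes carry too little postural
#' information and are discarded; the boundary is inclusive (exactly 120 s
#' is accepted).
#'
#' @param rec Recording tibble.
#' @param min_duration Minimum duration in seconds (default 120).
#' @return `TRUE` if the recording is retained, `FALSE` otherwise.
#' @export
validate_recording <- function(rec, min_duration = 120) {
  recording_duration(rec) >= min_duration
}

#' Down-sample a uniform recording to a low-resolution series
#'
#' Produces the 0.2 Hz (one sample per 5 s) visualization series by taking
#' the filtered sample nearest each 5-s grid point; the grid spans
#' `[0, last t]` inclusive. No additional anti-alias filtering is applied:
#' the series feeds plots, not analysis.
#'
#' @param rec Uniformly sampled (filtered) recording.
#' @param path Optional output CSV path; when given the series is written.
#' @param period Grid spacing in seconds (default 5, i.e. 0.2 Hz).
#' @return The low-resolution tibble (invisibly when `path` is given).
#' @export
write_low_res <- function(rec, path = NULL, period = 5) {
  if (nrow(rec) == 0L) stop("empty recording", call. = FALSE)
  if (!is_uniform(rec$t)) {
    stop("low-res export requires a uniformly sampled recording", call. = FALSE)
  }
  grid <- seq(0, recording_duration(rec), by = period)
  t0 <- min(rec$t)
  idx <- pmin(pmax(round((grid) / (if (nrow(rec) > 1) rec$t[2] - rec$t[1] else 1)) + 1, 1),
              nrow(rec))
  out <- rec[idx, c("t", "ax", "ay", "az")]
  out$t <- grid + t0
  if (!is.null(path)) {
    readr::write_csv(out, path)
    return(invisible(out))
  }
  out
}

is_uniform <- function(t, tol = 1e-6) {
  if (length(t) < 3L) return(TRUE)
  d <- diff(t)
  max(d) - min(d) < tol
}

#' Append a recording to a JSON-lines registry
#'
#' The registry mirrors the recordings index a monitoring app would keep:
#' one JSON object per line with the subject, start time, duration in
#' minutes and whether the raw file is still available. Recordings shorter
#' than two minutes are not registered (they are discarded upstream).
#'
#' @param path Registry file path (created if missing).
#' @param rec Recording tibble.
#' @param raw_available Logical flag.
#' @return The registry tibble, invisibly.
#' @export
registry_add <- function(path, rec, raw_available = TRUE) {
  if (!validate_recording(rec)) {
    stop("recording shorter than 2 min; discarded, not registered",
         call. = FALSE)
  }
  start <- attr(rec, "start_datetime")
  entry <- list(
    subject_id = attr(rec, "subject_id") %||% NA_character_,
    start_datetime = if (is.null(start)) NA_character_ else
      format(start, "%Y-%m-%dT%H:%M:%S"),
    duration_minutes = recording_duration(rec) / 60,
    raw_available = raw_available
  )
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = path, append = TRUE, sep = "")
  invisible(read_registry(path))
}

#' @rdname registry_add
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    return(tibble::tibble(subject_id = character(), start_datetime = character(),
                          duration_minutes = numeric(), raw_available = logical()))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    entry <- jsonlite::fromJSON(l)
    entry <- purrr::map(entry, function(x) if (is.null(x)) NA else x)
    tibble::as_tibble(entry)
  })
}

#' Read a pulse-oximetry CSV
#'
#' Expects header `t,spo2` with `t` in seconds and SpO2 in percent.
#' Physiologically impossible values are clipped to \[50, 100\] with a
#' warning, and samples following a gap longer than `max_gap` seconds are
#' flagged in the `gap` column.
#'
#' @param path CSV path.
#' @param max_gap Gap length (s) above which samples are flagged (default 10).
#' @return Tibble `t, spo2, gap` sorted by time.
#' @export
read_spo2 <- function(path, max_gap = 10) {
  df <- read_strict_csv(path, c("t", "spo2"))
  spo2_series(df$t, df$spo2, max_gap = max_gap)
}

#' @param t,spo2 Numeric vectors (seconds, percent).
#' @rdname read_spo2
#' @export
spo2_series <- function(t, spo2, max_gap = 10) {
  ord <- order(t)
  t <- t[ord]; spo2 <- spo2[ord]
  out_of_range <- spo2 < 50 | spo2 > 100
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " SpO2 values outside [50, 100] clipped", call. = FALSE)
    spo2 <- pmin(pmax(spo2, 50), 100)
  }
  tibble::tibble(
    t = t, spo2 = spo2,
    gap = c(FALSE, diff(t) > max_gap)
  )
}

#' Read or write an angle-series CSV (`t,sleep_angle,stand_angle,valid`)
#'
#' @param series Angle series tibble (see [compute_angles()]).
#' @param path CSV path.
#' @return `read_angles()` returns the angle series tibble; `write_angles()`
#'   returns `path` invisibly.
#' @export
write_angles <- function(series, path) {
  out <- series[, c("t", "sleep_angle", "stand_angle", "valid")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          t = readr::col_double(),
                          sleep_angle = readr::col_double(),
                          stand_angle = readr::col_double(),
                          valid = readr::col_logical()))
  tibble::as_tibble(df)
}

#' Read or write a desaturation-event CSV
#'
#' The on-disk dialect is `t_baseline,t_nadir,t_end,baseline,nadir,depth`
#' (an optional `assigned_angle` column is preserved). `read_desat_events()`
#' also ingests pre-scored vendor event lists in the same layout, bypassing
#' the detector.
#'
#' @param events Event tibble (see [detect_desaturations()]).
#' @param path CSV path.
#' @export
write_desat_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_desat_events
#' @export
read_desat_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t_baseline", "t_nadir", "t_end", "baseline", "nadir", "depth")
  if (!all(need %in% names(df))) {
    stop("event file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
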