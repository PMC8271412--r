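#' Process a raw recording into classified angles and a night summary
#'
#' The standard processing chain: validate duration (recordings under two
#' minutes are rejected), resample to a uniform 10 Hz, median filter with a
#' 60-s window, compute calibrated sleep/stand angles, classify positions
#' and summarize the night.
#'
#' @param rec Raw [accel_recording()].
#' @param rate Uniform resampling rate, Hz (default 10).
#' @param filter_window Median-filter window, seconds (default 60).
#' @param calibration,auto_calibrate,calibration_window Passed to
#'   [compute_angles()].
#' @param out_dir Optional directory; when given, writes `angles.csv`,
#'   `low_res.csv` and `summary.json`.
#' @return List with `angles` (classified `angle_series`), `summary`
#'   (`night_summary`) and `calibration`.
#' @export
process_recording <- function(rec, rate = 10, filter_window = 60,
                              calibration = NULL, auto_calibrate = TRUE,
                              calibration_window = 600, out_dir = NULL) {
  if (!validate_recording(rec)) {
    stop("recording shorter than 2 min: discarded", call. = FALSE)
  }
  uniform <- resample_uniform(rec, rate = rate)
  filtered <- median_filter(uniform, window = filter_window)
  angles <- compute_angles(filtered, calibration = calibration,
                           auto_calibrate = auto_calibrate,
                           calibration_window = calibration_window)
  angles <- classify_position(angles)
  summ <- summarize_positions(angles)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_angles(angles, file.path(out_dir, "angles.csv"))
    write_low_res(filtered, file.path(out_dir, "low_res.csv"))
    jsonlite::write_json(
      list(calibration = attr(angles, "calibration"),
           summary = generics::glance(summ),
           per_position = generics::tidy(summ)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(angles = angles, summary = summ,
       calibration = attr(angles, "calibration"))
}

#' Analyze a processed night against its pulse-oximetry trace
#'
#' Detects desaturation events, assigns each its sleep angle, computes the
#' whole-night ODI (laying time as the sleep-time denominator) and the
#' angle-resolved positional profile.
#'
#' @param angles Classified `angle_series` from [process_recording()].
#' @param spo2 SpO2 tibble (`t`, `spo2`), or `NULL` for a position-only
#'   profile.
#' @param cfg An [analysis_config()].
#' @param events Optional pre-scored event tibble (bypasses the detector,
#'   e.g. a vendor event list via [read_desat_events()]).
#' @param statistic Event-angle statistic, `"mean"` or `"median"`.
#' @param out_dir Optional directory; writes `events.csv`, `profile.csv`
#'   and `odi.json`.
#' @return List with `events`, `odi` (`odi_result` or `NULL`) and
#'   `profile` (`positional_profile`).
#' @export
analyze_night <- function(angles, spo2, cfg = analysis_config(),
                          events = NULL, statistic = c("mean", "median"),
                          out_dir = NULL) {
  statistic <- match.arg(statistic)
  if (!"position" %in% names(angles)) angles <- classify_position(angles)
  if (is.null(events)) {
    events <- if (is.null(spo2)) NULL else detect_desaturations(spo2)
  }
  odi <- NULL
  if (!is.null(events)) {
    events <- assign_event_angles(events, angles, statistic = statistic)
    laying_hours <- sum(angles$position %in% laying_levels) *
      series_dt(angles) / 3600
    hours <- if (laying_hours > 0) laying_hours else
      recording_duration(angles) / 3600
    odi <- compute_odi(events, hours)
  }
  profile <- positional_profile(angles, events, cfg)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(events)) {
      write_desat_events(events, file.path(out_dir, "events.csv"))
      jsonlite::write_json(generics::tidy(odi), file.path(out_dir, "odi.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    readr::write_csv(profile, file.path(out_dir, "profile.csv"), na = "")
  }
  list(events = events, odi = odi, profile = profile)
}
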