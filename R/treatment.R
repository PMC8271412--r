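#' Supine-avoidance vibration schedule
#'
#' Positional therapy discourages supine sleep with short vibrotactile
#' pulses: during every maximal run of supine-classified laying samples the
#' device vibrates for `pulse_duration` seconds every `pulse_interval`
#' seconds, starting as the run begins (optionally after a `grace` delay)
#' and stopping when the run ends. Pulses are suppressed while standing.
#'
#' @param series Classified `angle_series`.
#' @param pulse_duration Pulse length in seconds (default 0.3).
#' @param pulse_interval Seconds between pulse starts (default 3).
#' @param grace Delay in seconds after entering supine before the first
#'   pulse (default 0: fire immediately).
#' @return Tibble `t_start, duration` with one row per pulse; a night with
#'   no supine time yields zero rows.
#' @export
vibration_schedule <- function(series, pulse_duration = 0.3,
                               pulse_interval = 3, grace = 0) {
  if (!"position" %in% names(series)) series <- classify_position(series)
  dt <- series_dt(series)
  supine <- series$position == "SUPINE"
  if (!any(supine)) {
    return(tibble::tibble(t_start = numeric(), duration = numeric()))
  }
  r <- rle(as.logical(supine))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bouts <- tibble::tibble(start = starts[r$values], n = r$lengths[r$values])
  pulses <- purrr::pmap(bouts, function(start, n) {
    t0 <- series$t[start] + grace
    len <- n * dt - grace # remaining bout time occupied by supine samples
    if (len <= 0) return(numeric(0))
    # pulses strictly inside the run: t0 + k * interval for k * interval < len
    t0 + seq(0, by = pulse_interval, length.out = ceiling(len / pulse_interval))
  })
  ts <- as.numeric(unlist(pulses))
  tibble::tibble(t_start = ts,
                 duration = rep(pulse_duration, length(ts)))
}
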