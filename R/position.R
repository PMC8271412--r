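position_levels <- c("LEFT", "SUPINE", "RIGHT", "PRONE", "STANDING", "INVALID")
laying_levels <- c("LEFT", "SUPINE", "RIGHT", "PRONE")

#' Classify samples into discrete sleep positions
#'
#' Discretizes the calibrated angles into the four clinical sleep positions
#' plus standing. The quadrants are centered on the pure positions: LEFT on
#' \[-45, 45), SUPINE on \[45, 135), RIGHT on \[135, 180\] and (-180, -135),
#' PRONE on \[-135, -45). A sample is STANDING when the stand angle is
#' within 45 degrees of +-180 (or of 0: a "headstand" orientation cannot be
#' laying); laying requires `45 <= |stand| < 135`. Invalid samples get
#' INVALID.
#'
#' @param series An `angle_series` tibble (or vectors via `sleep`/`stand`).
#' @param boundaries Sleep-quadrant boundaries, degrees (default
#'   `c(-135, -45, 45, 135)` = symmetric quadrants).
#' @param stand_threshold Degrees from pure laying beyond which a sample is
#'   standing (default 45, i.e. `|stand| >= 135` or `|stand| < 45`).
#' @return `classify_position()` returns the series with a `position`
#'   factor column added; `classify_sample()` returns the factor for angle
#'   vectors.
#' @examples
#' classify_sample(90, 90)    # SUPINE
#' classify_sample(90, 178)   # STANDING
#' @export
classify_position <- function(series, boundaries = c(-135, -45, 45, 135),
                              stand_threshold = 45) {
  series$position <- classify_sample(series$sleep_angle, series$stand_angle,
                                     boundaries = boundaries,
                                     stand_threshold = stand_threshold,
                                     valid = series$valid %||% TRUE)
  series
}

#' @param sleep,stand Angle vectors in degrees, in (-180, 180].
#' @param valid Logical vector; `FALSE` forces INVALID.
#' @rdname classify_position
#' @export
classify_sample <- function(sleep, stand, boundaries = c(-135, -45, 45, 135),
                            stand_threshold = 45, valid = TRUE) {
  stopifnot(length(boundaries) == 4)
  valid <- rep_len(valid & !is.na(sleep) & !is.na(stand), length(sleep))
  standing <- abs(stand) >= (180 - stand_threshold) | abs(stand) < stand_threshold
  lab <- dplyr::case_when(
    !valid ~ "INVALID",
    standing ~ "STANDING",
    sleep >= boundaries[2] & sleep < boundaries[3] ~ "LEFT",
    sleep >= boundaries[3] & sleep < boundaries[4] ~ "SUPINE",
    sleep >= boundaries[1] & sleep < boundaries[2] ~ "PRONE",
    TRUE ~ "RIGHT"
  )
  factor(lab, levels = position_levels)
}

#' Summarize a night of classified sleep positions
#'
#' Produces the per-position summary clinicians read: minutes and
#' percentage of laying time in each sleep position, with the circular mean
#' and circular standard deviation of the sleep angle within each position,
#' plus laying/standing/invalid totals. Percentages use laying time as the
#' denominator, so the four position percentages sum to 100.
#'
#' @param series Classified `angle_series` (see [classify_position()]).
#' @return A `night_summary` object; use [generics::tidy()] for the
#'   per-position table and [generics::glance()] for the one-row night
#'   overview.
#' @export
summarize_positions <- function(series) {
  if (!"position" %in% names(series)) series <- classify_position(series)
  dt <- series_dt(series)
  per_min <- dt / 60
  pos <- series$position
  laying_min <- sum(pos %in% laying_levels) * per_min
  standing_min <- sum(pos == "STANDING") * per_min
  invalid_min <- sum(pos == "INVALID") * per_min
  total_min <- nrow(series) * per_min

  per_position <- tibble::tibble(position = factor(laying_levels,
                                                   levels = position_levels)) |>
    dplyr::mutate(
      minutes = purrr::map_dbl(.data$position, ~ sum(pos == .x) * per_min),
      percent = if (laying_min > 0) 100 * .data$minutes / laying_min else NA_real_,
      mean_angle = purrr::map_dbl(.data$position,
                                  ~ circ_mean(series$sleep_angle[pos == .x])),
      sd_angle = purrr::map_dbl(.data$position,
                                ~ circ_sd(series$sleep_angle[pos == .x]))
    )
  if (laying_min == 0) {
    warning("no laying time: position percentages undefined", call. = FALSE)
  }
  structure(
    list(
      per_position = per_position,
      laying_minutes = laying_min,
      standing_minutes = standing_min,
      invalid_minutes = invalid_min,
      total_minutes = total_min,
      laying_percent = if (total_min > 0)
        100 * laying_min / (laying_min + standing_min) else NA_real_,
      standing_percent = if (total_min > 0)
        100 * standing_min / (laying_min + standing_min) else NA_real_
    ),
    class = "night_summary"
  )
}

series_dt <- function(series) {
  rate <- attr(series, "rate")
  if (!is.null(rate) && is.finite(rate)) return(1 / rate)
  if (nrow(series) > 1) return(series$t[2] - series$t[1])
  0.1
}

#' @export
print.night_summary <- function(x, ...) {
  cat(sprintf("Night summary: %.1f min laying (%.1f%%), %.1f min standing\n",
              x$laying_minutes, x$laying_percent, x$standing_minutes))
  print(x$per_position)
  invisible(x)
}

#' Tidy a night summary into a per-position tibble
#'
#' @param x A `night_summary`.
#' @param ... Unused.
#' @return Tibble with one row per sleep position (minutes, percent of
#'   laying time, circular mean and SD of the sleep angle).
#' @export
tidy.night_summary <- function(x, ...) {
  x$per_position
}

#' One-row overview of a night summary
#'
#' @param x A `night_summary`.
#' @param ... Unused.
#' @return One-row tibble with laying/standing minutes and percentages and
#'   the supine percentage of laying time.
#' @export
glance.night_summary <- function(x, ...) {
  sup <- x$per_position$percent[x$per_position$position == "SUPINE"]
  tibble::tibble(
    total_minutes = x$total_minutes,
    laying_minutes = x$laying_minutes,
    standing_minutes = x$standing_minutes,
    invalid_minutes = x$invalid_minutes,
    laying_percent = x$laying_percent,
    standing_percent = x$standing_percent,
    supine_percent = sup
  )
}

#' Percentage split of laying minutes
#'
#' Shared helper behind the summary table: percentages of total laying
#' time for a vector of per-position minutes (the denominator is the sum
#' of the supplied minutes).
#'
#' @param minutes Numeric vector of per-position minutes.
#' @return Percentages summing to 100.
#' @examples
#' position_percent(c(29.2, 147.8, 89.6, 0)) # left/supine/right/prone
#' @export
position_percent <- function(minutes) {
  100 * minutes / sum(minutes)
}

#' Count position shifts during laying
#'
#' Number of label changes between consecutive laying samples, after
#' dropping dwell periods shorter than `min_dwell` seconds (debouncing:
#' the 60-s median filter already removes most flicker, the dwell guard
#' makes the count robust to the remainder).
#'
#' @param series Classified `angle_series`.
#' @param min_dwell Minimum dwell in seconds for a run to count (default 30).
#' @return Integer count of position shifts.
#' @export
count_shifts <- function(series, min_dwell = 30) {
  if (!"position" %in% names(series)) series <- classify_position(series)
  dt <- series_dt(series)
  lay <- as.character(series$position[series$position %in% laying_levels])
  if (length(lay) == 0L) return(0L)
  r <- rle(lay)
  keep <- r$lengths * dt >= min_dwell
  vals <- r$values[keep]
  if (length(vals) <= 1L) return(0L)
  sum(vals[-1] != vals[-length(vals)])
}
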