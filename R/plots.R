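#' Plot an angle series
#'
#' Sleep and stand angles over the night, colored by classified position.
#' For long nights the series is thinned to at most `max_points` points
#' before plotting.
#'
#' @param object Classified `angle_series`.
#' @param max_points Plot at most this many samples (default 5000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angle_series <- function(object, max_points = 5000, ...) {
  if (!"position" %in% names(object)) object <- classify_position(object)
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  df |>
    tidyr::pivot_longer(c("sleep_angle", "stand_angle"),
                        names_to = "which", values_to = "angle") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t / 3600, y = .data$angle,
                                 colour = .data$position)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::facet_wrap(~which, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = seq(-180, 180, 90), limits = c(-180, 180)) +
    ggplot2::labs(x = "time (h)", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an angle-resolved positional profile
#'
#' Four panels against the sleep angle: percentage of time, percentage of
#' desaturation events, local ODI (smoothed) and the event/position ratio.
#' Masked angles (no occupancy) are left blank.
#'
#' @param object A `positional_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.positional_profile <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::select("theta", "pct_position", "pct_de", "local_odi", "ratio") |>
    tidyr::pivot_longer(-"theta", names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric,
                      levels = c("pct_position", "pct_de", "local_odi", "ratio"),
                      labels = c("% position", "% events", "local ODI (1/h)",
                                 "ratio %DE/%position"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "sleep angle (deg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cohort heatmap of one profile statistic
#'
#' Renders a subject-by-angle matrix (see [profile_matrices()]) the way
#' positional-apnea cohorts are usually displayed: one row per subject,
#' masked cells black.
#'
#' @param m Subject-by-angle matrix.
#' @param title Plot title (e.g. the statistic's name).
#' @param path Optional PNG path; when given the plot is also written.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(m, title = NULL, path = NULL) {
  df <- tibble::as_tibble(m, rownames = "subject") |>
    tidyr::pivot_longer(-"subject", names_to = "theta", values_to = "value") |>
    dplyr::mutate(theta = as.numeric(.data$theta))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$subject,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "sleep angle (deg)", y = NULL, fill = NULL,
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 1 + 0.4 * nrow(m), dpi = 150)
  }
  p
}
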