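#' Detect oxygen desaturation events in an SpO2 series
#'
#' A desaturation event is a drop of at least `min_drop` percentage points
#' below the immediately preceding baseline, with the nadir reached within
#' `max_fall_time` seconds of the baseline sample. The detector works
#' nadir-first: candidate nadirs are local minima lying `min_drop` or more
#' below the running maximum of the preceding `max_fall_time` window; the
#' baseline sample is the last sample attaining that running maximum (its
#' value refined as the running maximum of the `baseline_window` seconds
#' before it), and the event ends at recovery to `baseline -
#' recovery_margin` points or, failing that, at the end of the series.
#' Overlapping candidates are merged, so one long hypoxic episode yields
#' one event. Slow drifts are rejected automatically: within any 120-s
#' window they never accumulate the full 3-point drop.
#'
#' @param spo2 Tibble with columns `t` (seconds, monotone) and `spo2`
#'   (percent), e.g. from [read_spo2()].
#' @param min_drop Minimum depth in percentage points (default 3, inclusive).
#' @param max_fall_time Maximum baseline-to-nadir time in seconds
#'   (default 120).
#' @param baseline_window Trailing window (s) whose maximum defines the
#'   baseline value at the fall start (default 30).
#' @param recovery_margin Recovery is reached at `baseline -
#'   recovery_margin` percent (default 1).
#' @return Tibble of events ordered by `t_baseline` with columns
#'   `t_baseline, t_nadir, t_end, baseline, nadir, depth`. An empty series
#'   is an error.
#' @export
detect_desaturations <- function(spo2, min_drop = 3, max_fall_time = 120,
                                 baseline_window = 30, recovery_margin = 1) {
  t <- spo2$t
  s <- spo2$spo2
  n <- length(s)
  if (n == 0L) stop("empty SpO2 series", call. = FALSE)
  if (n < 3L) return(empty_events())

  lo <- findInterval(t - max_fall_time, t) + 1L # first index inside window
  premax <- trailing_max(s, t, lo)

  local_min <- c(FALSE, s[2:(n - 1)] <= s[1:(n - 2)] & s[2:(n - 1)] <= s[3:n],
                 FALSE)
  cand <- which(local_min & premax - s >= min_drop)
  if (length(cand) == 0L) return(empty_events())

  events <- vector("list", length(cand))
  n_ev <- 0L
  prev_end <- 0L # index of previous event end
  for (j in cand) {
    if (j <= prev_end) next # inside the previous event
    # fall start: latest pre-nadir sample attaining the trailing max,
    # looking only after the previous event (events re-baseline)
    w <- lo[j]:(j - 1L)
    w <- w[w > prev_end]
    if (length(w) == 0L) next
    att <- w[s[w] == max(s[w])]
    b <- att[length(att)]
    # baseline value: running max of baseline_window before the fall start
    bw <- which(t >= t[b] - baseline_window & t <= t[b])
    bw <- bw[bw > prev_end]
    baseline <- max(s[bw])
    if (baseline - s[j] < min_drop) next
    # refine the fall start: with noisy plateaus the argmax can sit well
    # before the actual shoulder, so move to the last near-baseline sample
    # preceding the nadir (the "last sample before the fall")
    near <- w[w >= b & s[w] >= baseline - recovery_margin / 2]
    if (length(near)) b <- near[length(near)]
    # event end: recovery to baseline - margin after the candidate nadir
    after <- if (j < n) j + which(s[(j + 1):n] >= baseline - recovery_margin)
             else integer(0)
    end_i <- if (length(after)) after[1] else n
    # nadir: deepest sample between fall start and end, within the fall limit
    span <- (b + 1L):end_i
    span <- span[t[span] <= t[b] + max_fall_time]
    nad_i <- span[which.min(s[span])]
    n_ev <- n_ev + 1L
    events[[n_ev]] <- c(t[b], t[nad_i], t[end_i], baseline, s[nad_i])
    prev_end <- end_i
  }
  if (n_ev == 0L) return(empty_events())
  m <- do.call(rbind, events[seq_len(n_ev)])
  tibble::tibble(
    t_baseline = m[, 1], t_nadir = m[, 2], t_end = m[, 3],
    baseline = m[, 4], nadir = m[, 5], depth = m[, 4] - m[, 5]
  )
}

# Max of s over indices lo[j]..(j-1) for each j. For (near-)uniform series
# this reduces to a pmax over shifted copies (fast); otherwise fall back to
# an explicit loop.
trailing_max <- function(s, t, lo) {
  n <- length(s)
  k <- max(1L, max(seq_len(n) - lo))
  if (is_uniform(t, tol = 1e-6) && k < n) {
    out <- rep(-Inf, n)
    for (d in seq_len(k)) {
      idx <- (d + 1L):n
      out[idx] <- pmax(out[idx], s[idx - d])
    }
    # honour per-index window starts (first k samples have shorter windows,
    # handled exactly below)
    head_idx <- which(seq_len(n) - lo + 1L <= k & seq_len(n) <= k)
    for (j in head_idx) {
      if (j > 1L) out[j] <- max(s[lo[j]:(j - 1L)])
    }
    out[1] <- -Inf
    out
  } else {
    out <- rep(-Inf, n)
    for (j in 2:n) out[j] <- max(s[lo[j]:(j - 1L)])
    out
  }
}

empty_events <- function() {
  tibble::tibble(t_baseline = numeric(), t_nadir = numeric(),
                 t_end = numeric(), baseline = numeric(), nadir = numeric(),
                 depth = numeric())
}

#' Oxygen desaturation index and severity grade
#'
#' ODI is the number of desaturation events per hour of sleep. Severity
#' follows the AASM apnea-hypopnea bands applied to ODI: below 5 Healthy,
#' 5 to below 15 Mild, 15 to below 30 Moderate, 30 and above Severe.
#'
#' @param events Event tibble from [detect_desaturations()], or an integer
#'   event count.
#' @param sleep_hours Hours of sleep (laying time when available) used as
#'   the denominator; must be positive.
#' @return An `odi_result` list with `event_count`, `sleep_hours`, `odi`
#'   and `severity` (ordered factor); [generics::tidy()] returns it as a
#'   one-row tibble.
#' @examples
#' compute_odi(1967, 100.3) # whole-cohort pooled ODI
#' @export
compute_odi <- function(events, sleep_hours) {
  if (!is.numeric(sleep_hours) || sleep_hours <= 0) {
    stop("sleep_hours must be positive", call. = FALSE)
  }
  count <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  odi <- count / sleep_hours
  structure(
    list(event_count = count, sleep_hours = sleep_hours, odi = odi,
         severity = odi_severity(odi)),
    class = "odi_result"
  )
}

#' @param odi Numeric ODI values (events per hour).
#' @rdname compute_odi
#' @export
odi_severity <- function(odi) {
  cut(odi, breaks = c(-Inf, 5, 15, 30, Inf),
      labels = c("Healthy", "Mild", "Moderate", "Severe"),
      right = FALSE, ordered_result = TRUE)
}

#' @export
print.odi_result <- function(x, ...) {
  cat(sprintf("ODI: %.1f events/h (%d events over %.1f h) - %s\n",
              x$odi, x$event_count, x$sleep_hours, as.character(x$severity)))
  invisible(x)
}

#' @rdname compute_odi
#' @param x An `odi_result`.
#' @param ... Unused.
#' @export
tidy.odi_result <- function(x, ...) {
  tibble::tibble(event_count = x$event_count, sleep_hours = x$sleep_hours,
                 odi = x$odi, severity = as.character(x$severity))
}
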