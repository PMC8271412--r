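#' Specify a synthetic subject
#'
#' Describes one wearer for the night simulator: the discrete positions
#' they use (center sleep angle, von Mises angular jitter, log-normal dwell
#' distribution and a per-position Poisson desaturation rate), a
#' semi-Markov transition matrix between positions, sensor noise,
#' timestamp jitter, pulse-oximetry noise and desaturation-dip shape, the
#' response to vibrotactile treatment, and optional standing interruptions.
#'
#' Defaults emulate a moderate positional-OSA night: position centers near
#' the pooled per-position mean angles seen in sternum-worn recordings
#' (left ~30, supine 90, right ~160, prone ~-100 degrees), ~25-minute
#' dwells, accelerometer noise 0.02 g, SpO2 AR(1) noise with marginal SD
#' 0.3 percent around a 97 percent baseline, and trapezoidal desaturation
#' dips (descent 20-90 s, plateau 0-20 s, recovery 10-60 s, depth 4-8
#' points) at 25/h supine versus 5/h elsewhere.
#'
#' @param positions Tibble with columns `label`, `center`, `jitter_sd`
#'   (degrees), `dwell_meanlog`, `dwell_sdlog` (log-minutes) and
#'   `desat_rate` (events/hour).
#' @param transition Square matrix over `positions$label`; rows must sum
#'   to 1 with a zero diagonal.
#' @param noise_sigma Accelerometer noise SD in g.
#' @param timestamp_jitter Uniform timestamp jitter half-width in seconds
#'   around the nominal 10 Hz grid.
#' @param spo2_baseline,spo2_ar,spo2_sigma SpO2 baseline (percent), AR(1)
#'   coefficient and marginal noise SD (percent).
#' @param desat_depth,desat_descent,desat_plateau,desat_recovery Ranges
#'   (min, max) for dip depth (percent points) and phase durations (s).
#' @param compliance Probability of leaving the supine position per minute
#'   of vibration when treated.
#' @param standing_bouts Number of standing interruptions per night.
#' @param standing_minutes Typical standing bout length (minutes).
#' @param first_supine_minutes Minimum length of the opening supine bout;
#'   the calibration procedure assumes the wearer starts supine, so the
#'   generator always opens with a supine bout at least this long (under
#'   treatment the compliance clock starts only after this settling
#'   window).
#' @param calibration_jitter_sd Angular jitter (degrees) of the opening
#'   settling bout. Deliberately lying flat for calibration is more
#'   stereotyped than mid-sleep postures, so this is smaller than the
#'   per-bout jitter; it bounds the calibration error of every night.
#' @return A list of class `subject_model`.
#' @export
subject_model <- function(
    positions = default_positions(),
    transition = default_transition(positions$label),
    noise_sigma = 0.02,
    timestamp_jitter = 0.02,
    spo2_baseline = 97,
    spo2_ar = 0.8,
    spo2_sigma = 0.3,
    desat_depth = c(4, 8),
    desat_descent = c(20, 90),
    desat_plateau = c(0, 20),
    desat_recovery = c(10, 60),
    compliance = 0.9,
    standing_bouts = 1,
    standing_minutes = 2,
    first_supine_minutes = 12,
    calibration_jitter_sd = 2) {
  stopifnot(is.data.frame(positions),
            all(c("label", "center", "jitter_sd", "dwell_meanlog",
                  "dwell_sdlog", "desat_rate") %in% names(positions)),
            "SUPINE" %in% positions$label,
            all(positions$desat_rate >= 0),
            all(positions$jitter_sd > 0))
  transition <- as.matrix(transition)
  if (!isTRUE(all.equal(unname(rowSums(transition)),
                        rep(1, nrow(transition)), tolerance = 1e-8))) {
    stop("transition rows must sum to 1", call. = FALSE)
  }
  if (nrow(transition) != nrow(positions)) {
    stop("transition matrix must match positions", call. = FALSE)
  }
  dimnames(transition) <- list(positions$label, positions$label)
  structure(list(positions = positions, transition = transition,
                 noise_sigma = noise_sigma,
                 timestamp_jitter = timestamp_jitter,
                 spo2_baseline = spo2_baseline, spo2_ar = spo2_ar,
                 spo2_sigma = spo2_sigma, desat_depth = desat_depth,
                 desat_descent = desat_descent,
                 desat_plateau = desat_plateau,
                 desat_recovery = desat_recovery, compliance = compliance,
                 standing_bouts = standing_bouts,
                 standing_minutes = standing_minutes,
                 first_supine_minutes = first_supine_minutes,
                 calibration_jitter_sd = calibration_jitter_sd),
            class = "subject_model")
}

#' @rdname subject_model
#' @export
default_positions <- function() {
  tibble::tibble(
    label = c("LEFT", "SUPINE", "RIGHT", "PRONE"),
    center = c(30, 90, 160, -100),
    jitter_sd = c(6, 6, 6, 6),
    dwell_meanlog = log(c(25, 25, 25, 15)),
    dwell_sdlog = c(0.5, 0.5, 0.5, 0.5),
    desat_rate = c(5, 25, 5, 5)
  )
}

#' @param labels Position labels the matrix is defined over.
#' @rdname subject_model
#' @export
default_transition <- function(labels = c("LEFT", "SUPINE", "RIGHT", "PRONE")) {
  full <- matrix(c(
    0.00, 0.70, 0.20, 0.10, # from LEFT
    0.45, 0.00, 0.45, 0.10, # from SUPINE
    0.20, 0.70, 0.00, 0.10, # from RIGHT
    0.40, 0.20, 0.40, 0.00  # from PRONE
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("LEFT", "SUPINE", "RIGHT", "PRONE"),
                  c("LEFT", "SUPINE", "RIGHT", "PRONE")))
  m <- full[labels, labels, drop = FALSE]
  sweep(m, 1, rowSums(m), "/")
}

#' Scenario model for positional-rate recovery experiments
#'
#' Three positions (left/supine/right) with desaturation rates 40/h supine
#' and 5/h lateral, shorter supine dwells (so roughly a third of the night
#' is supine) and no standing interruptions: the configuration used to
#' check that the angle-resolved local ODI recovers planted rates.
#'
#' @return A `subject_model`.
#' @export
model_posa_recovery <- function() {
  pos <- tibble::tibble(
    label = c("LEFT", "SUPINE", "RIGHT"),
    center = c(30, 90, 150),
    jitter_sd = c(6, 6, 6),
    dwell_meanlog = log(c(35, 20, 35)),
    dwell_sdlog = c(0.4, 0.4, 0.4),
    desat_rate = c(5, 40, 5)
  )
  tr <- matrix(c(0, 0.7, 0.3,
                 0.5, 0, 0.5,
                 0.3, 0.7, 0), nrow = 3, byrow = TRUE)
  # severe-OSA nights cycle faster: shorter dips so 40/h fits in real time
  subject_model(positions = pos, transition = tr, standing_bouts = 0,
                desat_descent = c(15, 45), desat_plateau = c(0, 10),
                desat_recovery = c(10, 30))
}

#' Default four-subject cohort spanning the ODI severity bands
#'
#' One subject per severity class, with uniform (non-positional)
#' desaturation rates of about 1, 8, 20 and 45 events per hour, so the
#' full pipeline should grade them Healthy, Mild, Moderate and Severe.
#'
#' @return Named list of `subject_model`s.
#' @export
default_cohort <- function() {
  rates <- c(healthy = 1, mild = 8, moderate = 20, severe = 45)
  purrr::imap(rates, function(r, nm) {
    pos <- default_positions()
    pos$desat_rate <- rep(r, nrow(pos))
    if (r * (mean(c(20, 90)) + mean(c(0, 20)) + mean(c(10, 60))) > 3600) {
      # severe band needs the fast dip shape to fit its rate
      subject_model(positions = pos, desat_descent = c(15, 45),
                    desat_plateau = c(0, 10), desat_recovery = c(10, 30))
    } else {
      subject_model(positions = pos)
    }
  })
}

#' Simulate a full night of wearable data with known ground truth
#'
#' Generates one night: a semi-Markov sequence of position bouts (always
#' opening with a supine bout long enough for calibration), per-bout sleep
#' angles with von Mises jitter around the position centers, raw
#' accelerometry at a jittered ~10 Hz built by inverting the planar angle
#' formula (for sleep angle phi the gravity vector is `g * (cos phi, 0,
#' sin phi)`; standing bouts emit a -Y-dominant vector), plus a 1 Hz SpO2
#' trace with AR(1) noise and trapezoidal desaturation dips drawn from
#' per-position Poisson processes. When `treated`, supine bouts after the
#' first end after a compliance-model latency (geometric number of whole
#' vibration minutes plus a uniform settling fraction).
#'
#' Ground truth reports every planted bout and event both in the planted
#' frame and in the calibrated frame (angles shifted so the opening supine
#' bout maps to 90 degrees), because downstream angles are only
#' identifiable up to that per-recording calibration.
#'
#' @param model A [subject_model()].
#' @param hours Night duration in hours (default 8).
#' @param seed Integer seed; identical inputs give identical outputs.
#' @param treated Apply the vibration compliance model (default `FALSE`).
#' @return A list of class `sim_night`: `accel` (raw recording), `spo2`,
#'   and `truth` (list with `bouts`, `events`, `responses`,
#'   `calibration_offset`).
#' @export
simulate_night <- function(model, hours = 8, seed = 1, treated = FALSE) {
  stopifnot(inherits(model, "subject_model"), hours > 0)
  withr::with_seed(as.integer(seed), {
    dur <- hours * 3600
    bouts <- simulate_bouts(model, dur, treated)
    cal_offset <- wrap_angle(90 - bouts$angle[1])
    bouts$angle_cal <- ifelse(bouts$label == "STANDING", NA_real_,
                              wrap_angle(bouts$angle + cal_offset))
    bouts$label_cal <- ifelse(
      bouts$label == "STANDING", "STANDING",
      as.character(classify_sample(bouts$angle_cal, 90))
    )
    accel <- simulate_accel(model, bouts, dur)
    sp <- simulate_spo2(model, bouts, dur)
    structure(list(
      accel = accel,
      spo2 = sp$series,
      truth = list(bouts = bouts, events = sp$events,
                   responses = attr(bouts, "responses"),
                   calibration_offset = cal_offset),
      model = model, hours = hours, seed = as.integer(seed),
      treated = treated
    ), class = "sim_night")
  })
}

simulate_bouts <- function(model, dur, treated) {
  pos <- model$positions
  kappa <- (180 / (pi * pos$jitter_sd))^2
  labels <- pos$label
  cur <- "SUPINE"
  t <- 0
  rows <- list()
  responses <- list()
  first <- TRUE
  while (t < dur) {
    i <- match(cur, labels)
    dwell <- stats::rlnorm(1, pos$dwell_meanlog[i], pos$dwell_sdlog[i]) * 60
    if (first) dwell <- max(dwell, model$first_supine_minutes * 60)
    if (treated && cur == "SUPINE") {
      # the opening settling/calibration window is exempt; afterwards the
      # wearer leaves supine after a geometric number of vibration minutes
      grace <- if (first) model$first_supine_minutes * 60 else 0
      k <- stats::rgeom(1, model$compliance) # whole vibration minutes endured
      leave <- grace + (k + stats::runif(1, 0.2, 1)) * 60
      if (leave < dwell) {
        responses[[length(responses) + 1L]] <-
          c(bout_start = t, left_after = leave)
        dwell <- leave
      }
    }
    angle <- if (first) {
      # settling bout: deliberate supine posture, tighter than sleep jitter
      kap <- (180 / (pi * min(model$calibration_jitter_sd,
                              pos$jitter_sd[i])))^2
      rvonmises(1, pos$center[i], kap)
    } else {
      rvonmises(1, pos$center[i], kappa[i])
    }
    rows[[length(rows) + 1L]] <- list(start = t, end = min(t + dwell, dur),
                                      label = cur, angle = angle)
    t <- t + dwell
    cur <- sample(labels, 1, prob = model$transition[cur, ])
    first <- FALSE
  }
  bouts <- dplyr::bind_rows(rows)
  bouts <- insert_standing(model, bouts, dur)
  attr(bouts, "responses") <- if (length(responses)) {
    tibble::as_tibble(do.call(rbind, responses))
  } else {
    tibble::tibble(bout_start = numeric(), left_after = numeric())
  }
  bouts
}

# Replace the tail of `standing_bouts` randomly chosen laying bouts (never
# the calibration bout) with a standing interruption.
insert_standing <- function(model, bouts, dur) {
  n_stand <- model$standing_bouts
  if (n_stand < 1 || nrow(bouts) < 3) return(bouts)
  cand <- 2:(nrow(bouts) - 1)
  pick <- sort(cand[sample.int(length(cand), min(n_stand, length(cand)))])
  out <- list()
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    if (i %in% pick) {
      stand_len <- min(stats::rlnorm(1, log(model$standing_minutes), 0.4) * 60,
                       (b$end - b$start) / 2)
      cut <- b$end - stand_len
      out[[length(out) + 1L]] <- dplyr::mutate(b, end = cut)
      out[[length(out) + 1L]] <- tibble::tibble(
        start = cut, end = b$end, label = "STANDING", angle = NA_real_)
    } else {
      out[[length(out) + 1L]] <- b
    }
  }
  dplyr::bind_rows(out)
}

simulate_accel <- function(model, bouts, dur) {
  grid <- seq(0, dur, by = 0.1)
  n <- length(grid)
  t <- grid + stats::runif(n, -model$timestamp_jitter, model$timestamp_jitter)
  t[1] <- max(t[1], 0)
  bout_i <- findInterval(grid, bouts$start)
  ang <- bouts$angle[bout_i]
  standing <- bouts$label[bout_i] == "STANDING"
  rad <- ang * pi / 180
  ax <- ifelse(standing, 0, cos(rad))
  ay <- ifelse(standing, 0, 0)
  az <- ifelse(standing, 0, sin(rad))
  if (any(standing)) {
    tilt <- 10 * pi / 180
    ay[standing] <- -cos(tilt)
    az[standing] <- sin(tilt)
  }
  noise <- model$noise_sigma
  accel_recording(
    t = t,
    ax = ax + stats::rnorm(n, 0, noise),
    ay = ay + stats::rnorm(n, 0, noise),
    az = az + stats::rnorm(n, 0, noise),
    subject_id = "synthetic"
  )
}

# Desaturation events are a hard-core renewal process: within each laying
# bout, onset-to-onset cycles are (dip duration) + (exponential gap) with
# the gap mean chosen so the mean cycle equals 1/rate, giving a realized
# event rate equal to the nominal rate while keeping events separated by at
# least `min_gap` seconds (so each planted dip is individually scorable).
# If the nominal rate is too high to fit the model's dip durations, the gap
# floors at `min_gap` and the realized rate saturates, with a warning.
simulate_spo2 <- function(model, bouts, dur, min_gap = 5) {
  tt <- seq(0, dur, by = 1)
  n <- length(tt)
  phi <- model$spo2_ar
  innov_sd <- model$spo2_sigma * sqrt(1 - phi^2)
  noise <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
  s <- model$spo2_baseline + noise

  mean_dip <- mean(model$desat_descent) + mean(model$desat_plateau) +
    mean(model$desat_recovery)
  rate_of <- function(label) {
    model$positions$desat_rate[match(label, model$positions$label)]
  }
  if (any(model$positions$desat_rate > 0) &&
      3600 / max(model$positions$desat_rate) < mean_dip + min_gap) {
    warning("desaturation rate too high for the dip durations: ",
            "realized rate will saturate below nominal", call. = FALSE)
  }

  rows <- list()
  t_free <- 0
  for (i in seq_len(nrow(bouts))) {
    b <- bouts[i, ]
    if (b$label == "STANDING") next
    r <- rate_of(b$label)
    if (r <= 0) next
    gap_mean <- max(3600 / r - mean_dip - min_gap, min_gap)
    clock <- max(b$start, t_free)
    repeat {
      onset <- clock + stats::rexp(1, 1 / gap_mean)
      if (onset >= b$end) break
      descent <- stats::runif(1, model$desat_descent[1], model$desat_descent[2])
      plateau <- stats::runif(1, model$desat_plateau[1], model$desat_plateau[2])
      recovery <- stats::runif(1, model$desat_recovery[1],
                               model$desat_recovery[2])
      t_end <- onset + descent + plateau + recovery
      if (t_end > dur) break
      rows[[length(rows) + 1L]] <- tibble::tibble(
        onset = onset, t_nadir = onset + descent, t_end = t_end,
        depth = stats::runif(1, model$desat_depth[1], model$desat_depth[2]),
        descent = descent, plateau = plateau, recovery = recovery,
        label = b$label, angle = b$angle, angle_cal = b$angle_cal)
      clock <- t_end + min_gap
      t_free <- clock
    }
  }
  ev <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    onset = numeric(), t_nadir = numeric(), t_end = numeric(),
    depth = numeric(), descent = numeric(), plateau = numeric(),
    recovery = numeric(), label = character(), angle = numeric(),
    angle_cal = numeric())
  for (i in seq_len(nrow(ev))) {
    tau <- tt - ev$onset[i]
    dip <- pmin(pmax(tau / ev$descent[i], 0), 1) -
      pmin(pmax((tau - ev$descent[i] - ev$plateau[i]) / ev$recovery[i], 0), 1)
    s <- s - ev$depth[i] * dip
  }
  s <- pmin(pmax(s, 50), 100)
  list(series = tibble::tibble(t = tt, spo2 = s, gap = FALSE),
       events = ev)
}

#' @export
print.sim_night <- function(x, ...) {
  cat(sprintf("Simulated night: %.1f h, %d bouts, %d desaturation events%s\n",
              x$hours, nrow(x$truth$bouts), nrow(x$truth$events),
              if (x$treated) " (treated)" else ""))
  invisible(x)
}

#' Simulate a cohort of subjects and optionally write it to disk
#'
#' One accelerometry/SpO2 pair per model; when `dir` is given the raw CSVs
#' are written (`accel_<id>.csv`, `spo2_<id>.csv`) together with a
#' `manifest.json` listing per-subject seeds and planted event counts.
#'
#' @param models Named list of [subject_model()]s.
#' @param hours Night length in hours.
#' @param seed Base seed; subject i uses `seed + i`.
#' @param dir Optional output directory.
#' @param treated Logical, recycled over subjects.
#' @return Named list of `sim_night`s, invisibly when writing.
#' @export
simulate_cohort <- function(models, hours = 8, seed = 1, dir = NULL,
                            treated = FALSE) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("subject_", seq_along(models))
  treated <- rep_len(treated, length(models))
  sims <- purrr::imap(models, function(m, nm) {
    i <- match(nm, names(models))
    simulate_night(m, hours = hours, seed = as.integer(seed) + i,
                   treated = treated[i])
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest <- purrr::imap(sims, function(s, nm) {
      write_accel(s$accel, file.path(dir, paste0("accel_", nm, ".csv")))
      readr::write_csv(s$spo2[, c("t", "spo2")],
                       file.path(dir, paste0("spo2_", nm, ".csv")))
      list(subject = nm, seed = s$seed, treated = s$treated,
           hours = s$hours, n_events = nrow(s$truth$events))
    })
    jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(sims))
  }
  sims
}
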