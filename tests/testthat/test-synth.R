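test_that("simulation is deterministic in its seed", {
  m <- subject_model()
  a <- simulate_night(m, hours = 0.5, seed = 7)
  b <- simulate_night(m, hours = 0.5, seed = 7)
  expect_identical(a$accel, b$accel)
  expect_identical(a$spo2, b$spo2)
  expect_identical(a$truth$bouts, b$truth$bouts)
  c <- simulate_night(m, hours = 0.5, seed = 8)
  expect_false(identical(a$accel$ax, c$accel$ax))
})

test_that("invalid subject models are rejected", {
  bad_tr <- matrix(c(0, 0.5, 0.4, 0.1,
                     0.3, 0, 0.3, 0.3,
                     0.3, 0.3, 0, 0.4,
                     0.2, 0.2, 0.2, 0.4), 4, 4, byrow = TRUE)
  expect_error(subject_model(transition = bad_tr), "sum to 1")
  pos <- default_positions()
  pos$jitter_sd[1] <- 0
  expect_error(subject_model(positions = pos))
})

test_that("a noiseless supine night inverts to exactly 90 degrees", {
  pos <- tibble::tibble(label = "SUPINE", center = 90, jitter_sd = 1e-9,
                        dwell_meanlog = log(60), dwell_sdlog = 1e-9,
                        desat_rate = 0)
  m <- subject_model(positions = pos, transition = matrix(1),
                     noise_sigma = 0, timestamp_jitter = 0,
                     standing_bouts = 0)
  sim <- simulate_night(m, hours = 0.5, seed = 3)
  ang <- compute_angles(median_filter(resample_uniform(sim$accel), 60))
  expect_lt(max(abs(ang$sleep_angle - 90)), 1e-6)
  expect_lt(max(abs(ang$stand_angle - 90)), 1e-6)
})

test_that("bouts tile the night and ground truth carries both frames", {
  sim <- simulate_night(subject_model(), hours = 6, seed = 23)
  b <- sim$truth$bouts
  expect_equal(b$start[1], 0)
  expect_equal(b$end[nrow(b)], 6 * 3600)
  expect_equal(b$start[-1], b$end[-nrow(b)], tolerance = 1e-9)
  expect_equal(b$label[1], "SUPINE")
  expect_gte(b$end[1] - b$start[1], 12 * 60) # calibration bout
  lay <- b$label != "STANDING"
  expect_equal(wrap_angle(b$angle[lay] + sim$truth$calibration_offset),
               b$angle_cal[lay])
  expect_equal(sum(b$label == "STANDING"), 1)
})

test_that("planted desaturation counts follow the nominal per-position rates", {
  m <- model_posa_recovery()
  tot_obs <- tot_exp <- 0
  for (seed in 1:5) {
    sim <- simulate_night(m, hours = 8, seed = seed)
    b <- sim$truth$bouts
    hrs <- tapply((b$end - b$start) / 3600, b$label, sum)
    rate <- m$positions$desat_rate[match(names(hrs), m$positions$label)]
    tot_exp <- tot_exp + sum(hrs * rate)
    tot_obs <- tot_obs + nrow(sim$truth$events)
    # per-night dips stay separated and within the scoring envelope
    ev <- sim$truth$events
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$onset[-1] - ev$t_end[-nrow(ev)] >= 5 - 1e-9))
    expect_true(all(ev$depth >= 3))
    expect_true(all(ev$t_nadir - ev$onset <= 120))
  }
  # aggregated planted count within wide Poisson bounds of expectation
  expect_lt(abs(tot_obs - tot_exp), 3.3 * sqrt(tot_exp))
})

test_that("summaries recover planted per-position minutes within 2% of night", {
  for (seed in c(17, 18)) {
    sim <- simulate_night(subject_model(), hours = 8, seed = seed)
    proc <- process_recording(sim$accel)
    td <- tidy(proc$summary)
    b <- sim$truth$bouts
    b$minutes <- (b$end - b$start) / 60
    planted <- tapply(b$minutes, b$label_cal, sum)
    for (lab in c("LEFT", "SUPINE", "RIGHT", "PRONE")) {
      got <- td$minutes[td$position == lab]
      want <- if (lab %in% names(planted)) planted[[lab]] else 0
      expect_lt(abs(got - want), 0.02 * 8 * 60)
    }
    # and the angle series itself stays within 2 degrees RMS of the plant
    ang <- proc$angles
    bout_i <- findInterval(ang$t, b$start)
    lay <- b$label[bout_i] != "STANDING"
    err <- circ_dist(ang$sleep_angle[lay], b$angle_cal[bout_i][lay])
    expect_lt(sqrt(mean(err^2)), 2)
  }
})

test_that("treatment shortens supine time on the planted truth", {
  base <- simulate_night(subject_model(), hours = 8, seed = 29)
  trt <- simulate_night(subject_model(), hours = 8, seed = 29, treated = TRUE)
  sup_min <- function(sim) {
    b <- sim$truth$bouts
    sum((b$end - b$start)[b$label == "SUPINE"]) / 60
  }
  expect_lt(sup_min(trt), sup_min(base))
  expect_gt(nrow(trt$truth$responses), 0)
  # responses happen within the vibration compliance model's reach
  expect_true(all(trt$truth$responses$left_after > 0))
})

test_that("cohorts write one recording pair per subject plus a manifest", {
  dir <- withr::local_tempdir()
  models <- default_cohort()[1:3]
  sims <- simulate_cohort(models, hours = 0.25, seed = 5, dir = dir)
  expect_length(sims, 3)
  expect_setequal(
    list.files(dir),
    c(paste0("accel_", names(models), ".csv"),
      paste0("spo2_", names(models), ".csv"), "manifest.json"))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$subject, names(models))
  expect_equal(man$seed, 5 + 1:3)
  # written files parse back through the package readers
  rec <- read_accel(file.path(dir, "accel_healthy.csv"))
  expect_equal(nrow(rec), nrow(sims$healthy$accel))
})
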