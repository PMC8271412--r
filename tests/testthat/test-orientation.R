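test_that("resampling interpolates linearly onto the 10 Hz grid", {
  rec <- accel_recording(c(0, 1), c(0, 1), c(1, 0), c(0.5, 0.5))
  out <- resample_uniform(rec, rate = 10)
  expect_equal(out$t, seq(0, 1, 0.1))
  expect_equal(out$ax[out$t == 0.5], 0.5)
  expect_equal(out$ay, seq(1, 0, -0.1))

  # an already-uniform series passes through unchanged
  u <- accel_recording(seq(0, 5, 0.1), sin(seq(0, 5, 0.1)),
                       cos(seq(0, 5, 0.1)), rep(1, 51))
  out <- resample_uniform(u, rate = 10)
  expect_equal(out$ax, u$ax, tolerance = 1e-12)

  expect_error(resample_uniform(accel_recording(0, 1, 1, 1)), "2 samples")
})

test_that("resampling matches pointwise interpolation on jittered input", {
  withr::local_seed(7)
  t <- sort(runif(300, 0, 30))
  rec <- accel_recording(t, rnorm(300), rnorm(300), rnorm(300))
  out <- resample_uniform(rec, rate = 10)
  # independent per-point linear interpolation
  for (col in c("ax", "ay", "az")) {
    expected <- vapply(out$t, function(g) {
      src <- rec$t - rec$t[1]
      i <- max(which(src <= g + 1e-12))
      if (i == length(src)) return(rec[[col]][i])
      w <- (g - src[i]) / (src[i + 1] - src[i])
      (1 - w) * rec[[col]][i] + w * rec[[col]][i + 1]
    }, numeric(1))
    expect_lt(max(abs(out[[col]] - expected)), 1e-9)
  }
})

test_that("median filter is robust and matches the naive sliding median", {
  const <- accel_recording(seq(0, 10, 0.1), rep(1, 101), rep(0, 101),
                           rep(0.5, 101))
  expect_equal(median_filter(const, 6)$ax, rep(1, 101))

  spiky <- const
  spiky$ax[50] <- 50
  expect_equal(median_filter(spiky, 6)$ax, rep(1, 101))

  withr::local_seed(31)
  n <- 1200 # two minutes at 10 Hz
  rec <- accel_recording(seq(0, by = 0.1, length.out = n),
                         rnorm(n), rnorm(n), cumsum(rnorm(n, sd = 0.1)))
  filt <- median_filter(rec, window = 60)
  half <- 300
  for (col in c("ax", "az")) {
    expect_equal(filt[[col]], naive_sliding_median(rec[[col]], half))
  }
  # window wider than the series still matches the truncated definition
  filt2 <- median_filter(rec[1:50, ], window = 60)
  expect_equal(filt2$ax, naive_sliding_median(rec$ax[1:50], half))

  expect_error(median_filter(rec, 0), "positive")
})

test_that("the planar angle follows the body-frame conventions", {
  expect_equal(raw_angle(0, 1, 1), 90)    # pure supine
  expect_equal(raw_angle(1, 0, 0), 0)     # pure left, sign(0) = +1
  expect_equal(raw_angle(0, -1, -1), -90) # pure prone
  expect_equal(raw_angle(-1, 0, 1), 180)  # pure right, single representation
  expect_equal(raw_angle(sqrt(2) / 2, sqrt(2) / 2, 1), 45)
  expect_true(is.na(raw_angle(0, 0, 0))) # undefined orientation flagged
})

test_that("calibration maps the assumed-supine start onto 90 degrees", {
  mk <- function(sleep_raw) {
    tibble::tibble(t = seq(0, by = 0.1, length.out = length(sleep_raw)),
                   sleep_angle = sleep_raw, stand_angle = sleep_raw)
  }
  n <- 6001 # 600 s at 10 Hz
  expect_equal(calibrate_angles(mk(rep(80, n)))$theta_sleep, 10)
  expect_equal(calibrate_angles(mk(rep(90, n)))$theta_sleep, 0)

  withr::local_seed(5)
  noisy <- rnorm(n, 95, 3)
  cal <- calibrate_angles(mk(noisy))
  expect_lt(abs(cal$theta_sleep - (90 - naive_circ_mean(noisy))), 1e-9)
  expect_lt(abs(cal$theta_sleep + 5), 3 * 3 / sqrt(n))

  expect_warning(cal <- calibrate_angles(mk(rep(80, 100))), "zero offsets")
  expect_equal(cal$theta_sleep, 0)
})

test_that("angle computation recovers canonical orientations", {
  mk <- function(ax, ay, az, n = 3) {
    rec <- accel_recording(seq(0, by = 0.1, length.out = n),
                           rep(ax, n), rep(ay, n), rep(az, n))
    attr(rec, "rate") <- 10
    rec
  }
  supine <- compute_angles(mk(0, 0, 1), auto_calibrate = FALSE)
  expect_equal(supine$sleep_angle, rep(90, 3))
  expect_equal(supine$stand_angle, rep(90, 3))

  standing <- compute_angles(mk(0, -0.985, 0.174), auto_calibrate = FALSE)
  expect_true(all(abs(standing$stand_angle) > 165))

  left <- compute_angles(mk(1, 0, 0.05), auto_calibrate = FALSE)
  expect_lt(max(abs(left$sleep_angle - raw_angle(1, 0.05, 0.05))), 1e-12)
})

test_that("angles are scale invariant and always wrapped", {
  withr::local_seed(13)
  n <- 200
  rec <- accel_recording(seq(0, by = 0.1, length.out = n),
                         rnorm(n), rnorm(n), rnorm(n))
  a1 <- compute_angles(rec, auto_calibrate = FALSE)
  scaled <- accel_recording(rec$t, 2.5 * rec$ax, 2.5 * rec$ay, 2.5 * rec$az)
  a2 <- compute_angles(scaled, auto_calibrate = FALSE)
  expect_equal(a1$sleep_angle, a2$sleep_angle, tolerance = 1e-12)
  expect_equal(a1$stand_angle, a2$stand_angle, tolerance = 1e-12)

  for (off in c(-179, -90.5, 33.3, 179.9)) {
    a <- compute_angles(rec, calibration = list(theta_sleep = off,
                                                theta_stand = off))
    expect_true(all(a$sleep_angle > -180 & a$sleep_angle <= 180))
    expect_true(all(a$stand_angle > -180 & a$stand_angle <= 180))
  }
})

test_that("circular statistics behave on the wrap", {
  expect_equal(circ_mean(c(179, -179)), 180)
  expect_equal(circ_mean(c(85, 95)), 90)
  expect_equal(circ_sd(rep(42, 10)), 0)
  expect_equal(circ_median(c(170, 180, -170)), 180)
  withr::local_seed(3)
  x <- rnorm(2000, 20, 5)
  expect_lt(abs(circ_mean(x) - naive_circ_mean(x)), 1e-9)
  expect_lt(abs(circ_sd(x) - 5) / 5, 0.1) # near-linear regime matches SD
})
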