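test_that("%position windows are circular, inclusive, and conserve mass", {
  series <- make_angle_series(rep(90, 600))
  p <- pct_position(series)
  expect_equal(p$pct_position[p$theta == 90], 100)
  expect_equal(p$pct_position[p$theta == 97], 100) # 7 deg away: inside
  expect_equal(p$pct_position[p$theta == 98], 0)   # 8 deg away: outside
  expect_equal(p$pct_position[p$theta == 83], 100)
  expect_equal(p$pct_position[p$theta == 82], 0)
  expect_equal(sum(p$pct_position), 1500)

  expect_error(pct_position(make_angle_series(rep(90, 10), stand = 180)),
               "laying")
})

test_that("window counting matches the brute-force double loop", {
  withr::local_seed(83)
  for (rep in 1:3) {
    ang <- wrap_angle(runif(700, -180, 180))
    series <- make_angle_series(ang)
    p <- pct_position(series)
    expect_lt(max(abs(p$pct_position - naive_pct(ang))), 1e-9)
  }
  # wrap region and half-integer edge angles
  edge <- c(179.5, -179.5, 172.5, -180 + 1e-9, 180, 97.5, 82.5, 90)
  p <- pct_position(make_angle_series(edge))
  expect_equal(p$n_samples, naive_window_counts(edge))
})

test_that("event angles are the circular mean over the event span", {
  series <- make_angle_series(rep(90, 1200)) # 120 s at 10 Hz
  ev <- tibble::tibble(t_baseline = 10, t_nadir = 40, t_end = 60,
                       baseline = 97, nadir = 93, depth = 4)
  out <- assign_event_angles(ev, series)
  expect_equal(out$assigned_angle, 90)

  # an event spanning 179/-179 equally averages to 180, not 0; the span is
  # chosen so both sides contribute the same sample count
  wrap <- make_angle_series(rep(c(179, -179), 600))
  ev_bal <- dplyr::mutate(ev, t_end = 59.99)
  got <- assign_event_angles(ev_bal, wrap)$assigned_angle
  expect_lt(abs(circ_dist(got, 180)), 1e-6)

  # brute-force per-event check on a random series
  withr::local_seed(89)
  series <- make_angle_series(wrap_angle(cumsum(rnorm(3000, sd = 2))))
  evs <- tibble::tibble(t_baseline = c(5, 100, 250), t_nadir = c(20, 130, 270),
                        t_end = c(40, 160, 290), baseline = 97, nadir = 93,
                        depth = 4)
  out <- assign_event_angles(evs, series)
  for (i in seq_len(nrow(evs))) {
    idx <- series$t >= evs$t_baseline[i] & series$t <= evs$t_end[i]
    expect_lt(abs(circ_dist(out$assigned_angle[i],
                            naive_circ_mean(series$sleep_angle[idx]))), 1e-9)
  }

  # events outside the series span are dropped with a warning
  far <- tibble::tibble(t_baseline = 9000, t_nadir = 9050, t_end = 9100,
                        baseline = 97, nadir = 93, depth = 4)
  expect_warning(out <- assign_event_angles(far, series), "dropped")
  expect_equal(nrow(out), 0)

  # the median statistic is available for the alternative reading
  skewed <- make_angle_series(c(rep(80, 900), rep(140, 300)))
  ev2 <- tibble::tibble(t_baseline = 0, t_nadir = 60, t_end = 119.9,
                        baseline = 97, nadir = 93, depth = 4)
  expect_equal(assign_event_angles(ev2, skewed, statistic = "median")$assigned_angle,
               80)
})

test_that("%DE counts events in circular windows", {
  mk_ev <- function(angles) {
    tibble::tibble(t_baseline = seq_along(angles), t_nadir = seq_along(angles),
                   t_end = seq_along(angles), baseline = 97, nadir = 93,
                   depth = 4, assigned_angle = angles)
  }
  d <- pct_de(mk_ev(90))
  expect_equal(d$pct_de[d$theta == 90], 100)
  expect_equal(d$pct_de[d$theta == 0], 0)

  d <- pct_de(mk_ev(c(88, 90, 92, 160)))
  expect_equal(d$pct_de[d$theta == 90], 75)
  expect_equal(sum(d$pct_de), 1500)

  expect_warning(z <- pct_de(mk_ev(numeric(0))), "zero")
  expect_true(all(z$pct_de == 0))

  withr::local_seed(97)
  ang <- wrap_angle(runif(150, -180, 180))
  d <- pct_de(mk_ev(ang))
  expect_lt(max(abs(d$pct_de - naive_pct(ang))), 1e-9)
})

test_that("local ODI applies the hours denominator, floor, mask and smoothing", {
  mk_ev <- function(angles) {
    tibble::tibble(t_baseline = seq_along(angles), t_nadir = seq_along(angles),
                   t_end = seq_along(angles), baseline = 97, nadir = 93,
                   depth = 4, assigned_angle = angles)
  }
  # 60 min all at 90 with 5 events there: denominator is exactly 1 h
  series <- make_angle_series(rep(90, 36000))
  odi <- local_odi(mk_ev(rep(90, 5)), series)
  expect_equal(odi$local_odi_raw[odi$theta == 90], 5)
  expect_equal(odi$hours[odi$theta == 90], 1)

  # 5 min at 150 with 3 events: floor clamps the denominator to 1/6 h
  series <- make_angle_series(rep(150, 3000))
  odi <- local_odi(mk_ev(rep(150, 3)), series)
  expect_equal(odi$local_odi_raw[odi$theta == 150], 18)

  # angles never slept in are masked
  expect_true(is.na(odi$local_odi_raw[odi$theta == 0]))
  expect_false(odi$valid_odi[odi$theta == 0])
  expect_true(all(is.na(odi$local_odi[!odi$valid_odi])))

  # full stack equals the naive double-loop oracle on a random night
  withr::local_seed(101)
  ang <- wrap_angle(runif(6000, -180, 180) * rbinom(6000, 1, 0.7))
  series <- make_angle_series(ang)
  ev_ang <- wrap_angle(runif(40, -170, 170))
  odi <- local_odi(mk_ev(ev_ang), series)
  ref <- naive_local_odi(ev_ang, ang, dt = 0.1)
  expect_equal(odi$local_odi_raw, ref$raw, tolerance = 1e-9)
  expect_equal(odi$local_odi, ref$smoothed, tolerance = 1e-9)
})

test_that("the event/position ratio clamps small denominators and masks zeros", {
  cfg <- analysis_config()
  de <- tibble::tibble(theta = somnpose:::profile_grid(), pct_de = 50)
  pos <- tibble::tibble(theta = somnpose:::profile_grid(), pct_position = 25)
  expect_equal(ratio_de_position(de, pos, cfg)$ratio[1], 2)

  pos$pct_position <- 0.5
  de$pct_de <- 10
  expect_equal(ratio_de_position(de, pos, cfg)$ratio[1], 10) # clamped to 1%

  pos$pct_position <- 0
  r <- ratio_de_position(de, pos, cfg)
  expect_true(all(is.na(r$ratio)))
  expect_true(all(!r$valid_ratio))
})

test_that("profiles assemble and position-only profiles warn", {
  withr::local_seed(103)
  series <- make_angle_series(somnpose:::rvonmises(20000, 90, 80))
  ev <- tibble::tibble(t_baseline = c(100, 500), t_nadir = c(130, 540),
                       t_end = c(160, 580), baseline = 97, nadir = 93,
                       depth = 4)
  ev <- assign_event_angles(ev, series)
  prof <- positional_profile(series, ev)
  expect_s3_class(prof, "positional_profile")
  expect_equal(nrow(prof), 360)
  expect_equal(sum(prof$pct_position), 1500, tolerance = 1e-9)

  expect_warning(p2 <- positional_profile(series, NULL), "limited")
  expect_true(all(is.na(p2$local_odi)))
})

test_that("cohort matrices stack, render, and round-trip their masks", {
  withr::local_seed(107)
  mk_prof <- function(center) {
    series <- make_angle_series(somnpose:::rvonmises(20000, center, 60))
    ev <- tibble::tibble(t_baseline = c(60, 900), t_nadir = c(90, 940),
                         t_end = c(120, 980), baseline = 97, nadir = 93,
                         depth = 4)
    positional_profile(series, assign_event_angles(ev, series))
  }
  profs <- list(a = mk_prof(90), b = mk_prof(-30))
  mats <- profile_matrices(profs)
  expect_named(mats, c("pct_de", "pct_position", "ratio", "local_odi"))
  expect_true(all(vapply(mats, function(m) all(dim(m) == c(2, 360)), logical(1))))
  expect_true(anyNA(mats$local_odi)) # unexplored angles stay masked

  dir <- withr::local_tempdir()
  paths <- write_profile_matrices(profs, dir)
  expect_length(paths, 4)
  back <- read_profile_matrix(paths[["local_odi"]])
  expect_equal(unname(back), unname(mats$local_odi), tolerance = 1e-9)

  p <- plot_profile_heatmap(mats$local_odi, "local ODI")
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(profs$a), "ggplot")
})
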