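test_that("ordinal days are leap-normalized onto 1..365", {
  expect_equal(ordinal_day(as.POSIXct("2019-01-01", tz = "UTC")), 1)
  expect_equal(ordinal_day(as.POSIXct("2019-02-28", tz = "UTC")), 59)
  expect_equal(ordinal_day(as.POSIXct("2020-02-28", tz = "UTC")), 59)
  expect_equal(ordinal_day(as.POSIXct("2020-02-29", tz = "UTC")), 59)
  expect_equal(ordinal_day(as.POSIXct("2019-03-01", tz = "UTC")), 60)
  expect_equal(ordinal_day(as.POSIXct("2020-03-01", tz = "UTC")), 60)
  expect_equal(ordinal_day(as.POSIXct("2019-12-31", tz = "UTC")), 365)
  expect_equal(ordinal_day(as.POSIXct("2020-12-31", tz = "UTC")), 365)
})

test_that("initiation is back-calculated at the assumed travel rate", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  # 580 km / 58 km/h = 10 h
  p <- move_north(bl, bn, 580)
  est <- mk_est(p[1], p[2], 10, 14)
  bc <- back_calculate_initiation(est, bl, bn, thr)
  expect_true(bc$back_calculated)
  expect_equal(as.numeric(difftime(est$arrival, bc$time, units = "hours")),
               10, tolerance = 1e-6)
  # 1392 km -> 24 h
  p <- move_north(bl, bn, 1392)
  est <- mk_est(p[1], p[2], 10, 14)
  bc <- back_calculate_initiation(est, bl, bn, thr)
  expect_equal(as.numeric(difftime(est$arrival, bc$time, units = "hours")),
               24, tolerance = 1e-6)
  # inside the buffer: departure, no calculation
  p <- move_north(bl, bn, 200)
  est <- mk_est(p[1], p[2], 10, 14)
  bc <- back_calculate_initiation(est, bl, bn, thr)
  expect_false(bc$back_calculated)
  expect_equal(bc$time, est$departure)
})

test_that("breeding arrival is forward-calculated symmetrically", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  p <- move_north(bl, bn, 580)
  est <- mk_est(p[1], p[2], 140, 144)
  fc <- forward_calculate_arrival(est, bl, bn, thr)
  expect_true(fc$forward_calculated)
  expect_equal(as.numeric(difftime(fc$time, est$departure,
                                   units = "hours")), 10,
               tolerance = 1e-6)
  p <- move_north(bl, bn, 1392)
  est <- mk_est(p[1], p[2], 140, 144)
  fc <- forward_calculate_arrival(est, bl, bn, thr)
  expect_equal(as.numeric(difftime(fc$time, est$departure,
                                   units = "hours")), 24,
               tolerance = 1e-6)
  p <- move_north(bl, bn, 200)
  est <- mk_est(p[1], p[2], 140, 144)
  fc <- forward_calculate_arrival(est, bl, bn, thr)
  expect_false(fc$forward_calculated)
  expect_equal(fc$time, est$arrival)
})

test_that("winter arrival is the first long stop south of the winter latitude", {
  thr <- flyway_thresholds()
  est <- mk_est(c(60, 44), c(150, 120), c(1, 10), c(5, 60))
  expect_equal(find_winter_arrival(est, thr), 2)
  # a 41-day stop does not open winter; the next long stop does
  est <- mk_est(c(44, 40), c(120, 118), c(10, 55), c(51, 115))
  expect_equal(find_winter_arrival(est, thr), 2)
  # no qualifying stop (too far north)
  est <- mk_est(46, 120, 10, 110)
  expect_true(is.na(find_winter_arrival(est, thr)))
})

test_that("winter spans through the last long southern stop", {
  thr <- flyway_thresholds()
  # single long stop then northward staging
  est <- mk_est(c(44, 50), c(120, 140), c(10, 165), c(160, 170))
  expect_equal(find_winter_end(est, 1, thr), 1)
  # two long stops with a short one between: all three are winter
  est <- mk_est(c(44, 42, 43, 55), c(120, 118, 121, 140),
                c(10, 75, 90, 155), c(70, 85, 150, 160))
  ws <- find_winter_arrival(est, thr)
  expect_equal(ws, 1)
  expect_equal(find_winter_end(est, ws, thr), 3)
  # a trailing short southern stop belongs to north migration
  est <- mk_est(c(44, 43, 50), c(120, 121, 140),
                c(10, 165, 190), c(160, 185, 195))
  expect_equal(find_winter_end(est, 1, thr), 1)
})

test_that("segmentation recovers truth labels on a clean synthetic bird", {
  cfg <- make_paper_like_config(
    n_birds = c(sakhalina = 3), seed = 41,
    positional_noise_sd_km = 0, spurious_stop_rate = 0,
    reversal_rate = 0, partial_truncation_prob = 0)
  sim <- simulate_population(cfg)
  for (id in names(sim$tracks)) {
    rf <- refine_track(sim$tracks[[id]])
    seg <- segment_track(rf)
    expect_equal(seg$status, "complete")
    expect_equal(seg$labels, sim$truth[[id]]$stops$label)
    expect_equal(as.numeric(seg$winter_arrival),
                 as.numeric(sim$truth[[id]]$winter_arrival),
                 tolerance = 60)
    expect_equal(as.numeric(seg$winter_end),
                 as.numeric(sim$truth[[id]]$winter_end), tolerance = 60)
    # back-calculated initiation within minutes of the true departure
    expect_equal(as.numeric(seg$south_initiation),
                 as.numeric(sim$truth[[id]]$south_initiation),
                 tolerance = 600)
  }
})

test_that("truncated and winterless tracks yield partial segmentations", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  far <- move_north(bl, bn, 3000)
  wint <- move_north(bl, bn, 4000)  # ~34 N
  # truncated after winter arrival: south + winter, no north
  est <- mk_est(c(far[1], wint[1]), c(far[2], wint[2]),
                c(5, 20), c(10, 80))
  tr <- mk_track(est, bl, bn, complete = FALSE)
  seg <- segment_track(as_refined(tr), thr)
  expect_equal(seg$status, "no_north")
  expect_equal(seg$labels, c("south", "winter"))
  expect_true(is.na(seg$breeding_arrival))
  # no stop south of 45.5 N of winter length: unsegmentable as complete
  est <- mk_est(c(far[1], 50), c(far[2], 150), c(5, 20), c(10, 80))
  seg <- segment_track(as_refined(mk_track(est, bl, bn)), thr)
  expect_equal(seg$status, "no_winter")
  expect_equal(seg$labels, c("south", "south"))
})

test_that("period parameters: distances, additivity, degenerate winters", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  s1 <- move_north(bl, bn, 1000)
  s2 <- move_north(bl, bn, 2500)
  w1 <- move_north(bl, bn, 4300)
  est <- mk_est(c(s1[1], s2[1], w1[1]), c(s1[2], s2[2], w1[2]),
                c(2, 8, 15), c(5, 12, 160))
  tr <- mk_track(est, bl, bn)
  seg <- segment_track(as_refined(tr), thr)
  pp <- period_parameters(seg, as_refined(tr), thr)
  south <- pp[pp$period == "south", ]
  # additivity: breeding -> s1 -> s2 -> winter arrival, meridional path
  expect_equal(south$distance_km, 4300, tolerance = 1)
  expect_equal(south$n_stationary, 2)
  # single-stop winter: distance 0, speed 0
  winter <- pp[pp$period == "winter", ]
  expect_equal(winter$distance_km, 0)
  expect_equal(winter$speed_km_day, 0)
  expect_equal(winter$n_stationary, 1)
  # north: forward-calculated, distance = winter stop -> breeding leg
  north <- pp[pp$period == "north", ]
  expect_equal(north$distance_km, 4300, tolerance = 1)
  expect_equal(north$speed_km_day,
               north$distance_km / north$duration_days, tolerance = 1e-9)
  # period distance is never below the straight-line start-to-end distance
  expect_gte(south$distance_km + 1e-9,
             great_circle_km(bl, bn, w1[1], w1[2]))
})

test_that("a direct flight to the wintering grounds has zero south stops", {
  thr <- flyway_thresholds()
  bl <- 52.5; bn <- 143.2833
  w1 <- move_north(bl, bn, 2359)
  est <- mk_est(w1[1], w1[2], c(10), c(80))
  tr <- mk_track(est, bl, bn, subspecies = "actites")
  seg <- segment_track(as_refined(tr), thr)
  pp <- period_parameters(seg, as_refined(tr), thr)
  south <- pp[pp$period == "south", ]
  expect_equal(south$n_stationary, 0)
  expect_equal(south$distance_km, 2359, tolerance = 1)
  # duration is the back-calculated travel time; speed = distance/duration
  expect_equal(south$duration_days, 2359 / 58 / 24, tolerance = 1e-6)
})

test_that("within-individual ratios follow the north/south convention", {
  pp <- data.frame(period = c("south", "north"),
                   speed_km_day = c(100, 400),
                   n_stationary = c(4, 2))
  pp$stop_durations <- I(list(c(8, 10), c(4, 5)))
  r <- within_individual_ratios(pp)
  expect_equal(r$speed_ratio, 4)
  expect_equal(r$n_stationary_ratio, 0.5)
  expect_equal(r$stop_duration_ratio, 4.5 / 9)
  pp$n_stationary <- c(0, 2)
  pp$speed_km_day <- c(0, 400)
  r <- within_individual_ratios(pp)
  expect_true(is.na(r$speed_ratio))
  expect_true(is.na(r$n_stationary_ratio))
})

test_that("raising the winter duration threshold can only delay winter arrival", {
  set.seed(43)
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 10, sakhalina = 10), seed = 44)
  tracks <- simulate_population(cfg)$tracks
  thr1 <- flyway_thresholds()
  thr2 <- flyway_thresholds(winter_min_days = 60)
  for (tr in tracks) {
    rf <- suppressWarnings(refine_track(tr, thr1))
    i1 <- find_winter_arrival(rf$track$estimates, thr1)
    i2 <- find_winter_arrival(rf$track$estimates, thr2)
    if (!is.na(i1) && !is.na(i2)) expect_gte(i2, i1)
    if (is.na(i1)) expect_true(is.na(i2))
  }
})

test_that("labels partition all non-breeding estimates of a complete track", {
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 10, sakhalina = 8, kistchinski = 4), seed = 45,
    partial_truncation_prob = 0)
  sim <- simulate_population(cfg)
  for (tr in sim$tracks) {
    rf <- suppressWarnings(refine_track(tr))
    seg <- segment_track(rf)
    expect_equal(length(seg$labels), nrow(rf$track$estimates))
    expect_true(all(seg$labels %in%
                      c("south", "winter", "north", "breeding")))
    if (seg$status == "complete") {
      core <- seg$labels[seg$labels != "breeding"]
      expect_true(all(nzchar(core)))
      # contiguous blocks in annual-cycle order
      expect_equal(core, core[order(match(core,
                                          c("south", "winter", "north")))])
    }
  }
})
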