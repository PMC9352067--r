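test_that("proximity merging combines close stops and collapses chains", {
  thr <- flyway_thresholds()
  # two stops 300 km apart: unchanged
  est <- mk_est(c(0, 0), c(0, eq_deg(300)), c(1, 5), c(3, 9))
  out <- merge_proximal(est, thr)
  expect_equal(nrow(out$estimates), 2)
  expect_length(out$events, 0)

  # stops 100 km apart merge to their spherical midpoint, d1-d9
  est <- mk_est(c(0, 0), c(0, eq_deg(100)), c(1, 5), c(3, 9))
  out <- merge_proximal(est, thr)
  expect_equal(nrow(out$estimates), 1)
  mid <- mean_location(c(0, 0), c(0, eq_deg(100)))
  expect_equal(out$estimates$lat, mid[["lat"]], tolerance = 1e-9)
  expect_equal(out$estimates$lon, mid[["lon"]], tolerance = 1e-9)
  expect_equal(out$estimates$arrival, d2t(1))
  expect_equal(out$estimates$departure, d2t(9))

  # chain A-B 200 km, B-C 200 km (A-C 400 km): collapses to one stop
  est <- mk_est(c(0, 0, 0), c(0, eq_deg(200), eq_deg(400)),
                c(1, 5, 11), c(3, 9, 14))
  out <- merge_proximal(est, thr)
  expect_equal(nrow(out$estimates), 1)
  expect_equal(out$estimates$arrival, d2t(1))
  expect_equal(out$estimates$departure, d2t(14))
})

test_that("merging iterates to a fixed point when a centroid drifts into range", {
  thr <- flyway_thresholds()
  # A and B merge; their centroid is within 250 km of C although neither
  # A nor B was
  a <- c(0, 0)
  b <- c(2.2, 0)                      # ~245 km north of A
  cc <- c(1.1, eq_deg(230))           # ~230 km east of the A-B centroid
  expect_gt(great_circle_km(a[1], a[2], cc[1], cc[2]), 250)
  expect_gt(great_circle_km(b[1], b[2], cc[1], cc[2]), 250)
  est <- mk_est(c(a[1], b[1], cc[1]), c(a[2], b[2], cc[2]),
                c(1, 4, 8), c(3, 6, 12))
  out <- merge_proximal(est, thr)
  expect_equal(nrow(out$estimates), 1)
  expect_equal(length(out$events), 2)  # two merge passes
})

test_that("post-merge consecutive gaps are at least the merge threshold", {
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 15, sakhalina = 10), seed = 31)
  tracks <- simulate_population(cfg)$tracks
  thr <- flyway_thresholds()
  for (tr in tracks) {
    est <- merge_proximal(tr$estimates, thr)$estimates
    n <- nrow(est)
    if (n > 1) {
      gaps <- great_circle_km(est$lat[-n], est$lon[-n],
                              est$lat[-1], est$lon[-1])
      expect_gte(min(gaps), thr$merge_km)
    }
  }
})

test_that("pre-departure estimates are dropped up to the first distant stop", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  at_km <- function(km) move_north(bl, bn, km)
  # two near stops (100, 180 km) then a distant one: first two dropped
  p1 <- at_km(100); p2 <- at_km(180); p3 <- at_km(400)
  est <- mk_est(c(p1[1], p2[1], p3[1]), c(p1[2], p2[2], p3[2]),
                c(1, 4, 8), c(3, 6, 12))
  out <- drop_prebreeding(est, bl, bn, thr)
  expect_equal(nrow(out$estimates), 1)
  expect_equal(out$estimates$arrival, d2t(8))
  # first stop already 300 km away: unchanged
  p1 <- at_km(300)
  est <- mk_est(p1[1], p1[2], 1, 3)
  expect_equal(nrow(drop_prebreeding(est, bl, bn, thr)$estimates), 1)
  # all stops inside the buffer: empty plus warning
  p1 <- at_km(100); p2 <- at_km(200)
  est <- mk_est(c(p1[1], p2[1]), c(p1[2], p2[2]), c(1, 4), c(3, 6))
  expect_warning(out <- drop_prebreeding(est, bl, bn, thr), "buffer")
  expect_equal(nrow(out$estimates), 0)
})

test_that("polar estimates are dropped up to the first sub-polar stop", {
  thr <- flyway_thresholds()
  est <- mk_est(c(70, 68, 60, 68), c(150, 150, 150, 150),
                c(1, 4, 8, 12), c(3, 6, 10, 14))
  out <- drop_polar(est, thr)
  expect_equal(nrow(out$estimates), 2)     # later polar stop retained
  expect_equal(out$estimates$lat, c(60, 68))
  # all already south: unchanged
  est <- mk_est(c(60, 55), c(150, 145), c(1, 5), c(3, 8))
  expect_equal(nrow(drop_polar(est, thr)$estimates), 2)
  # the boundary is strict ("south of 66.7")
  est <- mk_est(66.7, 150, 1, 3)
  expect_equal(nrow(drop_polar(est, thr)$estimates), 0)
})

test_that("the protected estimate is the farthest winter-length stop", {
  thr <- flyway_thresholds()
  bl <- 70; bn <- -150
  p1 <- move_north(bl, bn, 3000); p2 <- move_north(bl, bn, 7000)
  p3 <- move_north(bl, bn, 6500)
  # only p2 has a >= 42-day stationary period
  est <- mk_est(c(p1[1], p2[1], p3[1]), c(p1[2], p2[2], p3[2]),
                c(1, 10, 80), c(3, 60, 85))
  pr <- protected_index(est, bl, bn, thr)
  expect_equal(pr$index, 2)
  expect_false(pr$flagged)
  # two winter-length stops: the farther wins
  est <- mk_est(c(p1[1], p2[1], p3[1]), c(p1[2], p2[2], p3[2]),
                c(1, 10, 80), c(3, 60, 130))
  expect_equal(protected_index(est, bl, bn, thr)$index, 2)
  # no winter-length stop: farthest overall, flagged
  est <- mk_est(c(p1[1], p2[1]), c(p1[2], p2[2]), c(1, 10), c(3, 20))
  pr <- protected_index(est, bl, bn, thr)
  expect_equal(pr$index, 2)
  expect_true(pr$flagged)
})

test_that("turning filter removes spikes and spares the protected terminus", {
  thr <- flyway_thresholds()
  # straight equatorial run: all angles 180, unchanged
  est <- mk_est(rep(0, 4), c(0, 5, 10, 15), c(1, 5, 9, 13), c(3, 7, 11, 15))
  out <- turning_filter(est, 10, 0, thr)
  expect_equal(nrow(out$estimates), 4)
  expect_length(out$events, 0)

  # overshoot-and-return (0 -> 10 -> 6 -> 20 along the equator): the
  # overshoot tip has angle 0, is removed, and its days are absorbed by
  # the spatially nearer survivor (the return stop at 6)
  est <- mk_est(c(0, 0, 0, 0), c(0, 10, 6, 20),
                c(1, 5, 9, 14), c(3, 7, 12, 16))
  out <- turning_filter(est, 50, 0, thr)
  expect_equal(nrow(out$estimates), 3)
  expect_equal(out$events[[1]]$index, 2)
  expect_equal(out$events[[1]]$absorbed_by, "next")
  expect_equal(out$estimates$lon, c(0, 6, 20))
  expect_equal(out$estimates$arrival[2], d2t(5))  # extended over the tip
  expect_equal(out$estimates$departure[2], d2t(12))

  # a reversal at the winter terminus (farthest >= 42-day stop) survives
  est <- mk_est(c(0, 0, 0, 0), c(0, 10, 20, 12),
                c(1, 5, 9, 60), c(3, 7, 55, 63))
  out <- turning_filter(est, 2, 0, thr)
  expect_equal(nrow(est), nrow(out$estimates))
  expect_length(out$events, 0)
})

test_that("refinement is idempotent; merging and absorption conserve day coverage", {
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 25, sakhalina = 15, kistchinski = 10),
    seed = 32)
  tracks <- simulate_population(cfg)$tracks
  thr <- flyway_thresholds()
  for (tr in tracks) {
    rf <- suppressWarnings(refine_track(tr, thr))
    rf2 <- suppressWarnings(refine_track(rf$track, thr))
    expect_length(rf2$provenance, 0)
    expect_equal(rf2$track$estimates, rf$track$estimates)
    # day coverage under the two absorbing operations never decreases
    m <- merge_proximal(tr$estimates, thr)
    expect_gte(union_days(m$estimates) + 1e-9, union_days(tr$estimates))
    tf <- turning_filter(m$estimates, tr$breeding_lat, tr$breeding_lon,
                         thr)
    expect_gte(union_days(tf$estimates) + 1e-9, union_days(m$estimates))
  }
})

test_that("provenance replay reproduces the refined estimates exactly", {
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 15, sakhalina = 10), seed = 33,
    spurious_stop_rate = 0.5, reversal_rate = 0.5)
  tracks <- simulate_population(cfg)$tracks
  for (tr in tracks) {
    rf <- suppressWarnings(refine_track(tr))
    replayed <- replay_provenance(tr$estimates, rf$provenance)
    expect_equal(replayed, rf$track$estimates, tolerance = 1e-12)
  }
})

test_that("corruption-free tracks pass refinement unchanged", {
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 10, sakhalina = 8, kistchinski = 4,
                actites = 2),
    seed = 34, positional_noise_sd_km = 0, spurious_stop_rate = 0,
    reversal_rate = 0, partial_truncation_prob = 0)
  sim <- simulate_population(cfg)
  for (id in names(sim$tracks)) {
    rf <- refine_track(sim$tracks[[id]])
    expect_length(rf$provenance, 0)
    expect_equal(rf$track$estimates[c("lat", "lon")],
                 sim$truth[[id]]$stops[c("lat", "lon")],
                 tolerance = 1e-9)
  }
})

test_that("refinement output is pinned on a 25-track golden corpus", {
  golden <- utils::read.csv(test_path("golden_refined.csv"),
                            stringsAsFactors = FALSE)
  cfg <- make_paper_like_config(
    n_birds = c(arcticola = 10, sakhalina = 10, kistchinski = 5),
    seed = 2024)
  tracks <- simulate_population(cfg)$tracks
  refined <- lapply(tracks, function(tr)
    suppressWarnings(refine_track(tr))$track)
  rows <- do.call(rbind, lapply(refined, function(tr) {
    if (!nrow(tr$estimates)) return(NULL)
    data.frame(bird_id = tr$bird_id,
               lat = round(tr$estimates$lat, 6),
               lon = round(tr$estimates$lon, 6),
               arrival = as.numeric(tr$estimates$arrival),
               departure = as.numeric(tr$estimates$departure),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  expect_equal(nrow(rows), nrow(golden))
  expect_equal(rows$bird_id, golden$bird_id)
  expect_equal(rows$lat, golden$lat, tolerance = 1e-5)
  expect_equal(rows$lon, golden$lon, tolerance = 1e-5)
  expect_equal(rows$arrival, golden$arrival, tolerance = 1)
  expect_equal(rows$departure, golden$departure, tolerance = 1)
})
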