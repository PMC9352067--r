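# Ground-truth-annotated synthetic Dunlin-like tracks with
# geolocator-style corruption. The generator emits tracks in the same form
# the reader produces, together with truth records carrying the real stop
# sequence, period labels, and boundary dates, so every downstream stage
# can be scored against known truth without any external data.

move_point <- function(lat, lon, bearing_deg, dist_km) {
  lat <- unname(lat); lon <- unname(lon)
  la <- lat * pi / 180
  th <- bearing_deg * pi / 180
  d <- dist_km / EARTH_RADIUS_KM
  la2 <- asin(sin(la) * cos(d) + cos(la) * sin(d) * cos(th))
  lo2 <- lon * pi / 180 +
    atan2(sin(th) * sin(d) * cos(la), cos(d) - sin(la) * sin(la2))
  c(lat = la2 * 180 / pi, lon = normalize_lon(lo2 * 180 / pi))
}

# isotropic spherical-normal jitter: independent N(0, sd) east and north
# displacements applied on the sphere
jitter_point <- function(lat, lon, sd_km) {
  lat <- unname(lat); lon <- unname(lon)
  if (sd_km <= 0) return(c(lat = lat, lon = lon))
  dx <- rnorm(1, 0, sd_km); dy <- rnorm(1, 0, sd_km)
  move_point(lat, lon, atan2(dx, dy) * 180 / pi, sqrt(dx^2 + dy^2))
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- rlnorm(n, meanlog, sdlog)
  for (i in seq_len(100)) {
    bad <- out < lo | out > hi
    if (!any(bad)) break
    out[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(out, lo), hi)
}

day_to_time <- function(year, day) {
  as.POSIXct(sprintf("%d-01-01", year), tz = "UTC") + (day - 1) * 86400
}

#' Synthetic-population configuration
#'
#' Describes, per subspecies, the breeding site, one or more itinerary
#' variants (ordered south-migration waypoints, winter site sequence with
#' winter-time shares, north-migration waypoints, and a variant
#' probability), and the timing distributions; plus population-level
#' corruption settings that emulate geolocator data: isotropic positional
#' error, spurious short stops, out-and-back reversals, missing estimates
#' north of 66.7 degrees N, and partial-track truncation.
#'
#' @param subspecies named list; see [make_paper_like_config()] for the
#'   shipped example of the structure.
#' @param spread_km biological scatter (km) of true stop locations around
#'   their itinerary waypoints.
#' @param positional_noise_sd_km per-axis positional error (km) added to
#'   emitted stop locations.
#' @param spurious_stop_rate expected number of spurious 2-4-day stops
#'   inserted per track at jittered leg midpoints.
#' @param reversal_rate expected number of out-and-back reversal stops
#'   inserted per track.
#' @param polar_suppression drop emitted stops at or north of 66.7 N
#'   (continuous daylight defeats light-level geolocation there).
#' @param partial_truncation_prob probability a track is truncated (dead
#'   tag) and marked partial.
#' @param tracking_year calendar year the tracks start in.
#' @param seed integer seed governing every draw.
#' @return object of class `flyway_sim_config`.
#' @export
flyway_sim_config <- function(subspecies,
                              spread_km = 50,
                              positional_noise_sd_km = 150,
                              spurious_stop_rate = 0.15,
                              reversal_rate = 0.10,
                              polar_suppression = TRUE,
                              partial_truncation_prob = 0.16,
                              tracking_year = 2018,
                              seed = 1L) {
  stopifnot(is.list(subspecies), length(subspecies) >= 1,
            spread_km >= 0, positional_noise_sd_km >= 0,
            spurious_stop_rate >= 0, reversal_rate >= 0,
            partial_truncation_prob >= 0, partial_truncation_prob <= 1)
  thr <- flyway_thresholds()
  for (nm in names(subspecies)) {
    sp <- subspecies[[nm]]
    stopifnot(sp$n_birds >= 0)
    probs <- vapply(sp$variants, `[[`, numeric(1), "prob")
    if (abs(sum(probs) - 1) > 1e-8)
      stop("variant probabilities for ", nm, " must sum to 1",
           call. = FALSE)
    for (v in sp$variants) {
      for (w in v$winter_sites)
        if (w[1] >= thr$winter_lat_deg)
          stop("winter site north of the winter latitude for ", nm,
               call. = FALSE)
      if (abs(sum(v$winter_split) - 1) > 1e-8 ||
          length(v$winter_split) != length(v$winter_sites))
        stop("winter_split must match winter_sites and sum to 1 for ", nm,
             call. = FALSE)
    }
  }
  structure(list(subspecies = subspecies, spread_km = spread_km,
                 positional_noise_sd_km = positional_noise_sd_km,
                 spurious_stop_rate = spurious_stop_rate,
                 reversal_rate = reversal_rate,
                 polar_suppression = polar_suppression,
                 partial_truncation_prob = partial_truncation_prob,
                 tracking_year = as.integer(tracking_year),
                 seed = as.integer(seed)),
            class = "flyway_sim_config")
}

#' Shipped configuration emulating the tracked Dunlin population
#'
#' Four subspecies with distinct Beringia breeding sites and staged
#' itineraries through shared East Asian-Australasian Flyway regions
#' (Sea of Okhotsk, North Sakhalin Island, Yellow Sea, Japan, East and
#' South China seas, inland China), with staggered south-migration
#' phenology (the southernmost breeder first), near-synchronous mid-May
#' north migration, and winter itineraries that give about half the
#' sakhalina population an inland-China wintering stage. Default sample
#' sizes match the tracked study population (59/35/5/1 birds).
#'
#' @param n_birds named integer vector of birds per subspecies.
#' @param seed integer seed.
#' @param ... overrides passed on to [flyway_sim_config()] (e.g.
#'   `positional_noise_sd_km`, `spurious_stop_rate`).
#' @return a `flyway_sim_config`.
#' @export
make_paper_like_config <- function(n_birds = c(arcticola = 59,
                                               sakhalina = 35,
                                               kistchinski = 5,
                                               actites = 1),
                                   seed = 1L, ...) {
  n_birds <- unlist(n_birds)  # accept a named list (e.g. from JSON config)
  # waypoint catalogue (lat, lon)
  ykd   <- c(61.5, -165.5)   # Yukon-Kuskokwim Delta, W Alaska
  neok  <- c(60.0, 156.0)    # NE Sea of Okhotsk
  neok2 <- c(61.0, 160.0)    # NE Sea of Okhotsk (spring staging)
  nsak  <- c(53.3, 143.3)    # N Sakhalin Island
  hok   <- c(42.9, 141.4)    # Hokkaido
  kwest <- c(36.8, 126.5)    # Korean west coast
  japan <- c(35.0, 136.8)    # central Japan
  ys    <- c(34.7, 119.8)    # Yellow Sea
  nwys  <- c(37.3, 119.5)    # NW Yellow Sea
  nchina <- c(39.2, 118.2)   # N China coast
  yrf   <- c(29.0, 116.0)    # Yangtze River Floodplain, inland China
  sys   <- c(33.9, 120.3)    # S Yellow Sea
  nys   <- c(38.8, 122.3)    # N Yellow Sea
  ecs31 <- c(31.2, 122.0)    # East China Sea (Yangtze mouth)
  ecs2  <- c(26.8, 119.8)    # East China Sea (Fujian)
  scs   <- c(22.5, 113.8)    # South China Sea (Pearl estuary)
  ysa   <- c(36.5, 122.3)    # Yellow Sea (Shandong)

  variant <- function(prob, south, winter, split, north)
    list(prob = prob, south_waypoints = south, winter_sites = winter,
         winter_split = split, north_waypoints = north)

  arcticola <- list(
    breeding_site = c(71.2652, -156.6359), site_id = "a",
    n_birds = unname(n_birds["arcticola"]),
    south_init_mean_day = 243, south_init_sd_days = 7,   # ~31 Aug
    south_stop_meanlog = log(13), south_stop_sdlog = 0.55,
    north_init_mean_day = 137, north_init_sd_days = 5,   # ~17 May
    north_stop_meanlog = log(5), north_stop_sdlog = 0.5,
    variants = list(
      variant(0.60, list(ykd, neok, nsak, kwest), list(ys), 1,
              list(nsak, neok2)),
      variant(0.25, list(ykd, neok, nsak, hok), list(japan), 1,
              list(nsak, neok2)),
      variant(0.15, list(ykd, neok, nsak, kwest), list(ecs31), 1,
              list(nsak, neok2))))

  sakhalina <- list(
    breeding_site = c(67.0647, -174.5), site_id = "e",
    n_birds = unname(n_birds["sakhalina"]),
    south_init_mean_day = 227, south_init_sd_days = 6,   # ~15 Aug
    south_stop_meanlog = log(8.5), south_stop_sdlog = 0.5,
    north_init_mean_day = 135, north_init_sd_days = 7,
    north_stop_meanlog = log(5), north_stop_sdlog = 0.5,
    variants = list(
      variant(0.46, list(neok2, nsak, hok), list(nchina, yrf, nwys),
              c(0.45, 0.30, 0.25), list(nsak, neok2)),
      variant(0.54, list(neok2, nsak, hok), list(kwest, sys, nys),
              c(0.45, 0.30, 0.25), list(nsak, neok2))))

  kistchinski <- list(
    breeding_site = c(56.2645, 162.5815), site_id = "g",
    n_birds = unname(n_birds["kistchinski"]),
    south_init_mean_day = 186, south_init_sd_days = 4,   # ~5 Jul
    south_stop_meanlog = log(15), south_stop_sdlog = 0.3,
    north_init_mean_day = 134, north_init_sd_days = 9,
    north_stop_meanlog = log(5), north_stop_sdlog = 0.5,
    variants = list(
      variant(1, list(nsak), list(ecs31, ecs2), c(0.6, 0.4), list(nsak))))

  actites <- list(
    breeding_site = c(52.5, 143.2833), site_id = "h",
    n_birds = unname(n_birds["actites"]),
    south_init_mean_day = 247, south_init_sd_days = 3,   # ~4 Sep
    south_stop_meanlog = log(8), south_stop_sdlog = 0.4,
    north_init_mean_day = 92, north_init_sd_days = 3,    # ~2 Apr
    north_stop_meanlog = log(15), north_stop_sdlog = 0.4,
    variants = list(
      variant(1, list(), list(ysa, scs), c(0.5, 0.5), list(sys, hok))))

  ssp <- list(arcticola = arcticola, sakhalina = sakhalina,
              kistchinski = kistchinski, actites = actites)
  ssp <- ssp[names(n_birds)[n_birds > 0]]
  flyway_sim_config(subspecies = ssp, seed = seed, ...)
}

simulate_bird <- function(bird_id, name, sp, config, thr) {
  yr <- config$tracking_year
  pick <- runif(1)
  probs <- cumsum(vapply(sp$variants, `[[`, numeric(1), "prob"))
  var_i <- which(pick <= probs + 1e-12)[1]
  v <- sp$variants[[var_i]]
  bs <- sp$breeding_site
  travel_days <- function(p1, p2)
    great_circle_km(p1[1], p1[2], p2[1], p2[2]) / thr$travel_kmh / 24

  t0 <- rnorm(1, sp$south_init_mean_day, sp$south_init_sd_days)
  stops <- list()
  cur_p <- bs; cur_t <- t0
  for (w in v$south_waypoints) {
    p <- jitter_point(w[1], w[2], config$spread_km)
    arr <- cur_t + travel_days(cur_p, p)
    dur <- rlnorm_trunc(1, sp$south_stop_meanlog, sp$south_stop_sdlog,
                        thr$min_stationary_days, thr$winter_min_days - 1)
    stops[[length(stops) + 1]] <-
      list(lat = p[1], lon = p[2], arr = arr, dep = arr + dur,
           label = "south")
    cur_p <- p; cur_t <- arr + dur
  }
  # winter: last site's departure is pinned to the drawn north initiation
  wsites <- lapply(v$winter_sites, function(w)
    jitter_point(w[1], w[2], config$spread_km))
  t1 <- rnorm(1, sp$north_init_mean_day, sp$north_init_sd_days) + 365
  m <- length(wsites)
  arr_w <- cur_t + travel_days(cur_p, wsites[[1]])
  winter_arrival <- arr_w
  travels <- if (m > 1) vapply(seq_len(m - 1), function(i)
    travel_days(wsites[[i]], wsites[[i + 1]]), numeric(1)) else numeric(0)
  usable <- t1 - arr_w - sum(travels)
  cur_t <- arr_w
  for (i in seq_len(m)) {
    dur <- if (i < m) v$winter_split[i] * usable
    else t1 - cur_t
    stops[[length(stops) + 1]] <-
      list(lat = wsites[[i]][1], lon = wsites[[i]][2],
           arr = cur_t, dep = cur_t + dur, label = "winter")
    cur_t <- cur_t + dur + (if (i < m) travels[i] else 0)
  }
  cur_p <- wsites[[m]]
  for (w in v$north_waypoints) {
    p <- jitter_point(w[1], w[2], config$spread_km)
    arr <- cur_t + travel_days(cur_p, p)
    dur <- rlnorm_trunc(1, sp$north_stop_meanlog, sp$north_stop_sdlog,
                        thr$min_stationary_days, thr$winter_min_days - 1)
    stops[[length(stops) + 1]] <-
      list(lat = p[1], lon = p[2], arr = arr, dep = arr + dur,
           label = "north")
    cur_p <- p; cur_t <- arr + dur
  }
  breeding_arrival <- cur_t + travel_days(cur_p, bs)

  truth_stops <- do.call(rbind, lapply(stops, function(s)
    data.frame(lat = unname(s$lat), lon = unname(s$lon),
               arrival = day_to_time(yr, s$arr),
               departure = day_to_time(yr, s$dep),
               label = s$label, stringsAsFactors = FALSE)))
  rownames(truth_stops) <- NULL
  truth <- list(bird_id = bird_id, subspecies = name, variant = var_i,
                stops = truth_stops,
                south_initiation = day_to_time(yr, t0),
                winter_arrival = day_to_time(yr, winter_arrival),
                winter_end = day_to_time(yr, t1),
                breeding_arrival = day_to_time(yr, breeding_arrival))

  # ---- corruption (truth is already frozen) ----
  em <- truth_stops[c("lat", "lon", "arrival", "departure")]
  if (config$positional_noise_sd_km > 0) {
    for (i in seq_len(nrow(em))) {
      p <- jitter_point(em$lat[i], em$lon[i], config$positional_noise_sd_km)
      em$lat[i] <- p[1]; em$lon[i] <- p[2]
    }
  }
  # spurious short stops at jittered leg midpoints
  n_sp <- rpois(1, config$spurious_stop_rate)
  for (s in seq_len(n_sp)) {
    n <- nrow(em)
    leg <- sample.int(n, 1)  # leg i: previous stop (or breeding) -> stop i
    prev <- if (leg == 1) bs else c(em$lat[leg - 1], em$lon[leg - 1])
    mid <- mean_location(c(prev[1], em$lat[leg]), c(prev[2], em$lon[leg]))
    mid <- jitter_point(mid[1], mid[2],
                        max(config$positional_noise_sd_km, 50))
    dur <- runif(1, 2, 4) * 86400
    if (leg == 1) {
      if (difftime(em$departure[1], em$arrival[1], units = "secs") <
          dur + 43200) next
      new <- data.frame(lat = mid[1], lon = mid[2],
                        arrival = em$arrival[1],
                        departure = em$arrival[1] + dur)
      em$arrival[1] <- em$arrival[1] + dur
    } else {
      if (difftime(em$departure[leg - 1], em$arrival[leg - 1],
                   units = "secs") < dur + 43200) next
      new <- data.frame(lat = mid[1], lon = mid[2],
                        arrival = em$departure[leg - 1] - dur,
                        departure = em$departure[leg - 1])
      em$departure[leg - 1] <- em$departure[leg - 1] - dur
    }
    em <- rbind(em, new)
    em <- em[order(em$arrival), , drop = FALSE]
    rownames(em) <- NULL
  }
  # out-and-back reversals
  n_rv <- rpois(1, config$reversal_rate)
  for (s in seq_len(n_rv)) {
    n <- nrow(em)
    if (n < 3) break
    cand <- which(vapply(2:(n - 1), function(i)
      great_circle_km(em$lat[i], em$lon[i], em$lat[i - 1], em$lon[i - 1]) >
        2.5 * thr$merge_km, logical(1))) + 1L
    if (!length(cand)) break
    i <- cand[sample.int(length(cand), 1)]
    dur <- runif(1, 2, 3) * 86400
    if (difftime(em$departure[i], em$arrival[i], units = "secs") <
        dur + 43200) next
    d <- great_circle_km(em$lat[i], em$lon[i], em$lat[i - 1], em$lon[i - 1])
    b <- initial_bearing_deg(em$lat[i], em$lon[i],
                             em$lat[i - 1], em$lon[i - 1])
    spike <- move_point(em$lat[i], em$lon[i], b, 0.6 * d)
    spike <- jitter_point(spike[1], spike[2],
                          config$positional_noise_sd_km / 2)
    new <- data.frame(lat = spike[["lat"]], lon = spike[["lon"]],
                      arrival = em$departure[i] - dur,
                      departure = em$departure[i])
    em$departure[i] <- em$departure[i] - dur
    em <- rbind(em, new)
    em <- em[order(em$arrival), , drop = FALSE]
    rownames(em) <- NULL
  }
  if (config$polar_suppression)
    em <- em[em$lat < thr$polar_lat_deg, , drop = FALSE]
  complete <- TRUE
  if (runif(1) < config$partial_truncation_prob && nrow(em) >= 3) {
    keep <- sample.int(nrow(em) - 2L, 1) + 1L
    em <- em[seq_len(keep), , drop = FALSE]
    complete <- FALSE
  }
  rownames(em) <- NULL
  track <- flyway_track(bird_id = bird_id, subspecies = name,
                        site_id = sp$site_id,
                        breeding_lat = bs[1], breeding_lon = bs[2],
                        estimates = em, complete = complete,
                        tracking_year = yr)
  list(track = track, truth = truth)
}

#' Simulate a population of tracks with ground truth
#'
#' Every bird follows its subspecies itinerary (breeding site -> south
#' waypoints -> winter site(s) -> north waypoints -> breeding site) with
#' jittered stop locations, lognormal stop durations, and travel at the
#' assumed flight speed; corruption (positional noise, spurious stops,
#' reversals, polar suppression, truncation) is applied only after the
#' truth record is frozen. Identical seed and configuration give
#' identical output.
#'
#' @param config a [flyway_sim_config()].
#' @return list with `tracks` (list of [flyway_track()]) and `truth`
#'   (parallel list of truth records: true stops with period labels and
#'   the true period boundary times).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "flyway_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  thr <- flyway_thresholds()
  tracks <- list(); truth <- list()
  for (name in names(config$subspecies)) {
    sp <- config$subspecies[[name]]
    for (b in seq_len(sp$n_birds)) {
      bird_id <- sprintf("%s_%03d", substr(name, 1, 4), b)
      res <- simulate_bird(bird_id, name, sp, config, thr)
      tracks[[bird_id]] <- res$track
      truth[[bird_id]] <- res$truth
    }
  }
  list(tracks = tracks, truth = truth)
}
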