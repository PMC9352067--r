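# Segmentation of refined tracks into south migration / winter / north
# migration, and the per-period migration parameters (initiation and
# arrival dates, duration, minimum distance, speed, stop statistics).

#' Leap-normalized ordinal day (1-365)
#'
#' Day-of-year index independent of year: 29 February maps to the same
#' index as 28 February and all later days shift down by one, so dates are
#' comparable across leap and common years.
#'
#' @param t POSIXct (UTC) vector.
#' @return integer vector in 1..365.
#' @export
ordinal_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  od <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ifelse(leap & od >= 60L, od - 1L, od)
}

#' Back-calculate south-migration initiation
#'
#' A bird whose first refined estimate lies beyond the breeding-site buffer
#' (e.g. because it bred north of 66.7 N, where geolocation fails) left the
#' breeding site before that estimate; the departure is back-calculated by
#' dividing the great-circle distance from the breeding site by the assumed
#' travel rate (58 km/h). If the first estimate is inside the buffer, its
#' departure is used directly.
#'
#' @param first_estimate one-row data.frame (`lat`, `lon`, `arrival`,
#'   `departure`).
#' @param breeding_lat,breeding_lon breeding site.
#' @param thresholds a [flyway_thresholds()] object.
#' @return list with `time` (POSIXct) and `back_calculated` (logical).
#' @export
back_calculate_initiation <- function(first_estimate, breeding_lat,
                                      breeding_lon,
                                      thresholds = flyway_thresholds()) {
  d <- great_circle_km(first_estimate$lat, first_estimate$lon,
                       breeding_lat, breeding_lon)
  if (d > thresholds$breed_buffer_km) {
    list(time = first_estimate$arrival - d / thresholds$travel_kmh * 3600,
         back_calculated = TRUE)
  } else {
    list(time = first_estimate$departure, back_calculated = FALSE)
  }
}

#' Forward-calculate breeding-ground arrival
#'
#' Mirror of [back_calculate_initiation()] applied to the last refined
#' estimate: travel time to the breeding site is added to its departure.
#'
#' @param last_estimate one-row data.frame.
#' @inheritParams back_calculate_initiation
#' @return list with `time` and `forward_calculated`.
#' @export
forward_calculate_arrival <- function(last_estimate, breeding_lat,
                                      breeding_lon,
                                      thresholds = flyway_thresholds()) {
  d <- great_circle_km(last_estimate$lat, last_estimate$lon,
                       breeding_lat, breeding_lon)
  if (d > thresholds$breed_buffer_km) {
    list(time = last_estimate$departure + d / thresholds$travel_kmh * 3600,
         forward_calculated = TRUE)
  } else {
    list(time = last_estimate$arrival, forward_calculated = FALSE)
  }
}

#' First winter estimate
#'
#' Index of the first estimate south of `winter_lat_deg` lasting at least
#' `winter_min_days`: south migration ends and winter begins on arrival
#' there.
#'
#' @inheritParams merge_proximal
#' @return integer index, or `NA_integer_` when no estimate qualifies (the
#'   track cannot be segmented as complete).
#' @export
find_winter_arrival <- function(estimates,
                                thresholds = flyway_thresholds()) {
  if (!nrow(estimates)) return(NA_integer_)
  ok <- estimates$lat < thresholds$winter_lat_deg &
    estimate_duration_days(estimates) >= thresholds$winter_min_days
  if (!any(ok)) NA_integer_ else which(ok)[1]
}

#' Last winter estimate
#'
#' Winter ends at the departure from the last estimate at or after the
#' winter start that is south of `winter_lat_deg` with duration of at least
#' `winter_min_days`. Short stops between long winter stops therefore
#' belong to winter, while short southern stops followed only by northern
#' ones belong to north migration. The rule needs look-ahead over the whole
#' remaining sequence; this is the unique formalization consistent with
#' both halves of the prose rule it implements.
#'
#' @inheritParams find_winter_arrival
#' @param winter_start_index index from [find_winter_arrival()].
#' @return integer index of the winter-terminus estimate.
#' @export
find_winter_end <- function(estimates, winter_start_index,
                            thresholds = flyway_thresholds()) {
  stopifnot(!is.na(winter_start_index))
  idx <- winter_start_index:nrow(estimates)
  ok <- estimates$lat[idx] < thresholds$winter_lat_deg &
    estimate_duration_days(estimates[idx, ]) >= thresholds$winter_min_days
  idx[max(which(ok))]
}

#' Segment a refined track into annual-cycle periods
#'
#' Labels every refined estimate `south`, `winter`, `north`, or `breeding`
#' (a terminal estimate back inside the breeding-site buffer) and derives
#' the period boundary times. Tracks without a qualifying winter stop, or
#' truncated before the return (dead tag), get a partial segmentation with
#' the missing boundaries set to `NA` and `status` saying why.
#'
#' @param refined a `flyway_refined` object from [refine_track()].
#' @param thresholds a [flyway_thresholds()] object.
#' @return object of class `flyway_segmentation`: list with `labels`,
#'   `south_initiation`, `back_calculated`, `winter_arrival`, `winter_end`,
#'   `breeding_arrival`, `forward_calculated`, `winter_start_index`,
#'   `winter_end_index`, `status` (one of `"complete"`, `"no_north"`,
#'   `"no_winter"`, `"empty"`).
#' @export
segment_track <- function(refined, thresholds = flyway_thresholds()) {
  stopifnot(inherits(refined, "flyway_refined"))
  tr <- refined$track
  est <- tr$estimates
  n <- nrow(est)
  na_t <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  out <- list(bird_id = tr$bird_id, labels = character(n),
              south_initiation = na_t, back_calculated = FALSE,
              winter_arrival = na_t, winter_end = na_t,
              breeding_arrival = na_t, forward_calculated = FALSE,
              winter_start_index = NA_integer_,
              winter_end_index = NA_integer_, status = "empty")
  class(out) <- "flyway_segmentation"
  if (n == 0) return(out)

  init <- back_calculate_initiation(est[1, ], tr$breeding_lat,
                                    tr$breeding_lon, thresholds)
  out$south_initiation <- init$time
  out$back_calculated <- init$back_calculated

  ws <- find_winter_arrival(est, thresholds)
  if (is.na(ws)) {
    out$labels <- rep("south", n)
    out$status <- "no_winter"
    return(out)
  }
  we <- find_winter_end(est, ws, thresholds)
  out$winter_start_index <- ws
  out$winter_end_index <- we
  out$winter_arrival <- est$arrival[ws]
  out$winter_end <- est$departure[we]
  labels <- character(n)
  if (ws > 1) labels[1:(ws - 1)] <- "south"
  labels[ws:we] <- "winter"
  if (we < n) {
    after <- (we + 1):n
    labels[after] <- "north"
    d_home <- great_circle_km(est$lat[after], est$lon[after],
                              tr$breeding_lat, tr$breeding_lon)
    back <- which(d_home < thresholds$breed_buffer_km)
    if (length(back)) {
      home <- after[back[1]]
      labels[home:n] <- "breeding"
      out$breeding_arrival <- est$arrival[home]
      out$forward_calculated <- FALSE
      out$status <- "complete"
    } else {
      fc <- forward_calculate_arrival(est[n, ], tr$breeding_lat,
                                      tr$breeding_lon, thresholds)
      out$breeding_arrival <- fc$time
      out$forward_calculated <- fc$forward_calculated
      out$status <- if (tr$complete) "complete" else "no_north"
    }
  } else {
    # track ends in winter
    if (tr$complete) {
      fc <- forward_calculate_arrival(est[n, ], tr$breeding_lat,
                                      tr$breeding_lon, thresholds)
      out$breeding_arrival <- fc$time
      out$forward_calculated <- fc$forward_calculated
      out$status <- "complete"
    } else {
      out$status <- "no_north"
    }
  }
  out$labels <- labels
  out
}

#' @export
print.flyway_segmentation <- function(x, ...) {
  cat(sprintf("<flyway_segmentation> %s [%s]: %s\n", x$bird_id, x$status,
              paste(x$labels, collapse = " ")))
  invisible(x)
}

period_distance <- function(path_lat, path_lon) {
  if (length(path_lat) < 2) return(0)
  n <- length(path_lat)
  sum(great_circle_km(path_lat[-n], path_lon[-n],
                      path_lat[-1], path_lon[-1]))
}

#' Per-period migration parameters
#'
#' Computes, for each of south migration, winter, and north migration:
#' initiation and arrival times, duration (days), minimum migration
#' distance (km, the sum of great-circle legs between sequential
#' stationary estimates), number of stationary estimates, days at each
#' stationary estimate, and speed (km/day). The south distance includes
#' the breeding-site-to-first-stop leg and the leg into the first winter
#' stop; the north distance starts at the winter terminus and includes the
#' final leg to the breeding site, so distances reflect the full journey
#' between breeding and wintering grounds. South `n_stationary` counts
#' migration stops only (the winter-arrival stop belongs to winter); a
#' bird that flew directly to its wintering grounds has `n_stationary = 0`
#' and distance equal to the single leg.
#'
#' @param segmentation a `flyway_segmentation`.
#' @param refined the matching `flyway_refined`.
#' @param thresholds a [flyway_thresholds()] object.
#' @param include_breeding_legs set `FALSE` to restrict distances to legs
#'   between labeled stops only.
#' @return data.frame with one row per period and columns `period`,
#'   `initiation`, `arrival`, `duration_days`, `distance_km`,
#'   `n_stationary`, `stop_durations` (list column), `speed_km_day`.
#'   Periods missing from a partial track have `NA` entries.
#' @export
period_parameters <- function(segmentation, refined,
                              thresholds = flyway_thresholds(),
                              include_breeding_legs = TRUE) {
  tr <- refined$track
  est <- tr$estimates
  lab <- segmentation$labels
  dur <- estimate_duration_days(est)
  na_t <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  row <- function(period, initiation, arrival, stops_idx, path_lat,
                  path_lon) {
    duration <- as.numeric(difftime(arrival, initiation, units = "days"))
    dist <- period_distance(path_lat, path_lon)
    speed <- if (is.na(duration)) NA_real_
    else if (duration > 0) dist / duration
    else if (dist == 0) 0 else NA_real_
    data.frame(period = period,
               initiation = if (is.null(initiation)) na_t else initiation,
               arrival = if (is.null(arrival)) na_t else arrival,
               duration_days = if (length(duration)) duration else NA_real_,
               distance_km = dist,
               n_stationary = length(stops_idx),
               stop_durations = I(list(dur[stops_idx])),
               speed_km_day = speed,
               stringsAsFactors = FALSE)
  }
  empty_row <- function(period) {
    data.frame(period = period, initiation = na_t, arrival = na_t,
               duration_days = NA_real_, distance_km = NA_real_,
               n_stationary = NA_integer_, stop_durations = I(list(NULL)),
               speed_km_day = NA_real_, stringsAsFactors = FALSE)
  }
  ws <- segmentation$winter_start_index
  we <- segmentation$winter_end_index

  south <- if (!is.na(ws)) {
    s_idx <- which(lab == "south")
    lat <- c(if (include_breeding_legs) tr$breeding_lat,
             est$lat[s_idx], est$lat[ws])
    lon <- c(if (include_breeding_legs) tr$breeding_lon,
             est$lon[s_idx], est$lon[ws])
    row("south", segmentation$south_initiation, segmentation$winter_arrival,
        s_idx, lat, lon)
  } else empty_row("south")

  winter <- if (!is.na(ws)) {
    w_idx <- ws:we
    row("winter", segmentation$winter_arrival, segmentation$winter_end,
        w_idx, est$lat[w_idx], est$lon[w_idx])
  } else empty_row("winter")

  north <- if (!is.na(we) && !is.na(segmentation$breeding_arrival)) {
    n_idx <- which(lab == "north")
    lat <- c(est$lat[we], est$lat[n_idx],
             if (include_breeding_legs) tr$breeding_lat)
    lon <- c(est$lon[we], est$lon[n_idx],
             if (include_breeding_legs) tr$breeding_lon)
    row("north", segmentation$winter_end, segmentation$breeding_arrival,
        n_idx, lat, lon)
  } else empty_row("north")

  out <- rbind(south, winter, north)
  rownames(out) <- NULL
  out
}

#' Within-individual north/south ratios
#'
#' Ratios of north-migration to south-migration speed, stop count, and
#' median stop duration for one bird. Undefined (NA) when the south value
#' is zero or a period is missing.
#'
#' @param params data.frame from [period_parameters()].
#' @return one-row data.frame with `speed_ratio`, `n_stationary_ratio`,
#'   `stop_duration_ratio`.
#' @export
within_individual_ratios <- function(params) {
  g <- function(period, colname) {
    v <- params[params$period == period, colname]
    if (!length(v)) NA else v[[1]]
  }
  ratio <- function(n, s) {
    if (is.na(n) || is.na(s) || s == 0) NA_real_ else n / s
  }
  med_dur <- function(period) {
    v <- unlist(params$stop_durations[params$period == period])
    if (!length(v)) NA_real_ else median(v)
  }
  data.frame(
    speed_ratio = ratio(g("north", "speed_km_day"),
                        g("south", "speed_km_day")),
    n_stationary_ratio = ratio(g("north", "n_stationary"),
                               g("south", "n_stationary")),
    stop_duration_ratio = ratio(med_dur("north"), med_dur("south")))
}

#' Per-bird, per-period parameter table
#'
#' Runs [segment_track()] and [period_parameters()] over a set of refined
#' tracks and stacks the results: the tabular analogue of a published
#' migration-characteristics table, one row per bird x period.
#'
#' @param refined_list list of `flyway_refined` objects.
#' @param thresholds a [flyway_thresholds()] object.
#' @return data.frame with `bird_id`, `subspecies`, `complete`, `flagged`,
#'   `status`, plus all [period_parameters()] columns and
#'   `median_stop_days`.
#' @export
parameter_table <- function(refined_list,
                            thresholds = flyway_thresholds()) {
  rows <- lapply(refined_list, function(rf) {
    seg <- segment_track(rf, thresholds)
    pp <- period_parameters(seg, rf, thresholds)
    pp$median_stop_days <- vapply(pp$stop_durations, function(v) {
      if (length(v)) median(v) else NA_real_
    }, numeric(1))
    pp$bird_id <- rf$track$bird_id
    pp$subspecies <- rf$track$subspecies
    pp$complete <- rf$track$complete
    pp$flagged <- rf$flagged
    pp$status <- seg$status
    pp
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and interquartile summary of migration parameters
#'
#' Per subspecies x period medians and 25th/75th percentiles (linear
#' interpolation) of duration, distance, stop count, stop duration, and
#' speed, plus median initiation/arrival dates on leap-normalized ordinal
#' days -- the package's analogue of a published summary table.
#'
#' @param params data.frame from [parameter_table()].
#' @return data.frame, one row per subspecies x period.
#' @export
summarize_parameters <- function(params) {
  params <- params[!is.na(params$duration_days), , drop = FALSE]
  med_iqr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    c(median(v), quantile(v, 0.25, names = FALSE),
      quantile(v, 0.75, names = FALSE))
  }
  key <- interaction(params$subspecies, params$period, drop = TRUE)
  rows <- lapply(split(params, key), function(g) {
    dur <- med_iqr(g$duration_days)
    dist <- med_iqr(g$distance_km)
    ns <- med_iqr(g$n_stationary)
    sd_ <- med_iqr(g$median_stop_days)
    sp <- med_iqr(g$speed_km_day)
    data.frame(subspecies = g$subspecies[1], period = g$period[1],
               n = nrow(g),
               initiation_median_day = median(ordinal_day(g$initiation)),
               arrival_median_day = median(ordinal_day(g$arrival)),
               duration_median = dur[1], duration_q1 = dur[2],
               duration_q3 = dur[3],
               distance_median = dist[1], distance_q1 = dist[2],
               distance_q3 = dist[3],
               n_stationary_median = ns[1], n_stationary_q1 = ns[2],
               n_stationary_q3 = ns[3],
               stop_days_median = sd_[1], stop_days_q1 = sd_[2],
               stop_days_q3 = sd_[3],
               speed_median = sp[1], speed_q1 = sp[2], speed_q3 = sp[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
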