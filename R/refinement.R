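# Three-step refinement of geolocator stationary estimates:
#   1. merge sequential estimates closer than merge_km (iterated to a fixed
#      point) and drop estimates before the bird first leaves a 250-km
#      buffer around its breeding site;
#   2. drop estimates before the bird first moves south of 66.7 N;
#   3. remove interior estimates with turning angle < 60 degrees, absorbing
#      their days into the spatially nearest neighbor, sparing the farthest
#      stop with a stationary period of at least 42 days (the winter
#      terminus, where a true reversal is expected).
# Boundary conventions are strict: "< 250 km", "south of 66.7" (strictly),
# "< 60 degrees", ">= 42 days".

new_event <- function(type, ...) c(list(type = type), list(...))

#' Merge sequential stationary estimates that are close together
#'
#' Collapses each maximal chain of consecutive estimates whose neighboring
#' pairs are closer than `merge_km` into a single estimate at the spherical
#' mean of the members, spanning the earliest arrival to the latest
#' departure. Merging repeats until no consecutive pair is below the
#' threshold: a merged centroid can newly fall within range of its
#' neighbor.
#'
#' @param estimates data.frame with `lat`, `lon`, `arrival`, `departure`,
#'   time-ordered.
#' @param thresholds a [flyway_thresholds()] object.
#' @param weight_by_duration if `TRUE`, the merged location is the
#'   stop-duration-weighted spherical mean instead of the plain mean.
#' @return list with refined `estimates` and a `events` provenance list.
#' @export
merge_proximal <- function(estimates, thresholds = flyway_thresholds(),
                           weight_by_duration = FALSE) {
  est <- estimates
  events <- list()
  repeat {
    n <- nrow(est)
    if (n < 2) break
    d <- great_circle_km(est$lat[-n], est$lon[-n], est$lat[-1], est$lon[-1])
    close <- d < thresholds$merge_km
    if (!any(close)) break
    i <- which(close)[1]
    j <- i
    while (j < n - 1 && close[j + 1]) j <- j + 1
    members <- i:(j + 1)
    w <- if (weight_by_duration)
      pmax(estimate_duration_days(est[members, ]), 1e-9) else NULL
    ctr <- mean_location(est$lat[members], est$lon[members], w)
    merged <- data.frame(lat = ctr[["lat"]], lon = ctr[["lon"]],
                         arrival = min(est$arrival[members]),
                         departure = max(est$departure[members]))
    events[[length(events) + 1]] <-
      new_event("merge", indices = members, result = merged)
    est <- rbind(est[seq_len(i - 1), , drop = FALSE], merged,
                 est[setdiff(seq_len(n), 1:(j + 1)), , drop = FALSE])
    rownames(est) <- NULL
  }
  list(estimates = est, events = events)
}

#' Drop estimates before departure from the breeding area
#'
#' Removes leading estimates up to (not including) the first estimate more
#' than `breed_buffer_km` from the breeding site. Later near-breeding
#' estimates (the return) are untouched.
#'
#' @inheritParams merge_proximal
#' @param breeding_lat,breeding_lon breeding site, decimal degrees.
#' @return list with `estimates` and `events`. If no estimate ever leaves
#'   the buffer the result is empty and a warning is raised.
#' @export
drop_prebreeding <- function(estimates, breeding_lat, breeding_lon,
                             thresholds = flyway_thresholds()) {
  est <- estimates
  events <- list()
  if (nrow(est)) {
    d <- great_circle_km(est$lat, est$lon, breeding_lat, breeding_lon)
    k <- which(d > thresholds$breed_buffer_km)[1]
    if (is.na(k)) {
      warning("no stationary estimate beyond the breeding-site buffer; ",
              "all estimates dropped", call. = FALSE)
      k <- nrow(est) + 1L
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) events[[i]] <- new_event("drop_prebreeding",
                                                         index = i)
      est <- est[seq_len(nrow(est)) >= k, , drop = FALSE]
      rownames(est) <- NULL
    }
  }
  list(estimates = est, events = events)
}

#' Drop estimates before the bird moves south of the polar latitude
#'
#' @inheritParams merge_proximal
#' @return list with `estimates` and `events`. Estimates after the first
#'   sub-polar one are retained regardless of latitude.
#' @export
drop_polar <- function(estimates, thresholds = flyway_thresholds()) {
  est <- estimates
  events <- list()
  if (nrow(est)) {
    k <- which(est$lat < thresholds$polar_lat_deg)[1]  # strictly south of
    if (is.na(k)) k <- nrow(est) + 1L
    if (k > 1) {
      for (i in seq_len(k - 1)) events[[i]] <- new_event("drop_polar",
                                                         index = i)
      est <- est[seq_len(nrow(est)) >= k, , drop = FALSE]
      rownames(est) <- NULL
    }
  }
  list(estimates = est, events = events)
}

#' Index of the protected (winter-terminus) estimate
#'
#' The estimate farthest from the breeding site among those with a
#' stationary period of at least `winter_min_days`; a natural reversal of
#' direction is expected there, so the turning-angle filter spares it. If
#' no estimate lasts that long the overall farthest estimate is returned
#' and the track is flagged for review.
#'
#' @inheritParams drop_prebreeding
#' @return list with `index` (integer, `NA` for an empty track) and
#'   `flagged` (logical).
#' @export
protected_index <- function(estimates, breeding_lat, breeding_lon,
                            thresholds = flyway_thresholds()) {
  if (nrow(estimates) == 0) return(list(index = NA_integer_, flagged = FALSE))
  d <- great_circle_km(estimates$lat, estimates$lon,
                       breeding_lat, breeding_lon)
  long <- estimate_duration_days(estimates) >= thresholds$winter_min_days
  if (any(long)) {
    idx <- which(long)[which.max(d[long])]
    list(index = idx, flagged = FALSE)
  } else {
    list(index = which.max(d), flagged = TRUE)
  }
}

#' Turning-angle filter
#'
#' Repeatedly removes the interior estimate with the smallest turning angle
#' below `turn_min_deg` (smallest first, one at a time with recomputation,
#' so the sharpest artifacts go first and the procedure is deterministic),
#' absorbing its arrival-departure interval into the spatially nearest
#' surviving neighbor; ties break to the earlier neighbor. First and last
#' estimates have no defined angle and are exempt, as is the protected
#' winter-terminus estimate (see [protected_index()]).
#'
#' @inheritParams drop_prebreeding
#' @return list with `estimates`, `events`, and `flagged` (from the
#'   protected-index fallback).
#' @export
turning_filter <- function(estimates, breeding_lat, breeding_lon,
                           thresholds = flyway_thresholds()) {
  est <- estimates
  events <- list()
  flagged <- FALSE
  repeat {
    n <- nrow(est)
    if (n < 3) break
    prot <- protected_index(est, breeding_lat, breeding_lon, thresholds)
    flagged <- flagged || prot$flagged
    interior <- 2:(n - 1)
    ang <- turning_angle_deg(est$lat[interior - 1], est$lon[interior - 1],
                             est$lat[interior], est$lon[interior],
                             est$lat[interior + 1], est$lon[interior + 1])
    cand <- interior[ang < thresholds$turn_min_deg & interior != prot$index]
    if (!length(cand)) break
    i <- cand[which.min(ang[match(cand, interior)])]
    dprev <- great_circle_km(est$lat[i], est$lon[i],
                             est$lat[i - 1], est$lon[i - 1])
    dnext <- great_circle_km(est$lat[i], est$lon[i],
                             est$lat[i + 1], est$lon[i + 1])
    if (dprev <= dnext) {  # ties to the earlier neighbor
      est$departure[i - 1] <- max(est$departure[i - 1], est$departure[i])
      side <- "prev"
    } else {
      est$arrival[i + 1] <- min(est$arrival[i + 1], est$arrival[i])
      side <- "next"
    }
    events[[length(events) + 1]] <-
      new_event("drop_turning", index = i, absorbed_by = side)
    est <- est[-i, , drop = FALSE]
    rownames(est) <- NULL
  }
  list(estimates = est, events = events, flagged = flagged)
}

#' Refine a migration track
#'
#' Applies the full refinement: proximity merging and pre-departure drop,
#' polar drop, then the turning-angle filter, recording every merge and
#' drop in a provenance log. Refinement is idempotent: refining an
#' already-refined track leaves it unchanged with an empty log.
#'
#' @param track a [flyway_track()].
#' @param thresholds a [flyway_thresholds()] object.
#' @param weight_by_duration passed to [merge_proximal()].
#' @return object of class `flyway_refined`: list with `track` (the refined
#'   track), `provenance` (ordered event list), and `flagged` (no stop of
#'   winter duration was found; such tracks are excluded from network
#'   construction).
#' @export
refine_track <- function(track, thresholds = flyway_thresholds(),
                         weight_by_duration = FALSE) {
  stopifnot(inherits(track, "flyway_track"))
  s1 <- merge_proximal(track$estimates, thresholds, weight_by_duration)
  s1b <- drop_prebreeding(s1$estimates, track$breeding_lat,
                          track$breeding_lon, thresholds)
  s2 <- drop_polar(s1b$estimates, thresholds)
  s3 <- turning_filter(s2$estimates, track$breeding_lat, track$breeding_lon,
                       thresholds)
  out <- track
  out$estimates <- s3$estimates
  structure(list(track = out,
                 provenance = c(s1$events, s1b$events, s2$events, s3$events),
                 flagged = s3$flagged),
            class = "flyway_refined")
}

#' @export
print.flyway_refined <- function(x, ...) {
  cat(sprintf("<flyway_refined> %s: %d estimates, %d refinement events%s\n",
              x$track$bird_id, nrow(x$track$estimates),
              length(x$provenance),
              if (x$flagged) " [flagged: no winter-length stop]" else ""))
  invisible(x)
}

#' Replay a provenance log against raw estimates
#'
#' Applies the recorded merge/drop events, in order, to the raw estimate
#' table; the result must equal the refined estimates. Used to audit that
#' the provenance log fully explains a refinement.
#'
#' @param estimates raw estimate data.frame (pre-refinement).
#' @param provenance event list from [refine_track()].
#' @return the replayed estimate data.frame.
#' @export
replay_provenance <- function(estimates, provenance) {
  est <- estimates
  for (ev in provenance) {
    n <- nrow(est)
    est <- switch(ev$type,
      merge = {
        keep <- setdiff(seq_len(n), ev$indices)
        out <- rbind(est[keep[keep < min(ev$indices)], , drop = FALSE],
                     ev$result,
                     est[keep[keep > min(ev$indices)], , drop = FALSE])
        rownames(out) <- NULL
        out
      },
      drop_prebreeding = ,
      drop_polar = est[-1, , drop = FALSE],
      drop_turning = {
        i <- ev$index
        if (ev$absorbed_by == "prev")
          est$departure[i - 1] <- max(est$departure[i - 1], est$departure[i])
        else
          est$arrival[i + 1] <- min(est$arrival[i + 1], est$arrival[i])
        out <- est[-i, , drop = FALSE]
        rownames(out) <- NULL
        out
      },
      stop("unknown provenance event type: ", ev$type))
  }
  rownames(est) <- NULL
  est
}
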