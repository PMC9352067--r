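# Season-specific weighted migratory networks and daily occupancy
# profiles. Nodes and edges are weighted by the proportion of individuals
# of each subspecies that used a region, and that moved between region
# pairs; denominators are per-subspecies complete-track counts.

#' Assign estimates to flyway regions by nearest medoid
#'
#' Points that took part in the clustering keep their cluster membership;
#' new points go to the nearest medoid (ties to the lower region id).
#'
#' @param lat,lon estimate coordinates.
#' @param regions a `flyway_regions` object.
#' @return integer vector of region ids.
#' @export
assign_regions <- function(lat, lon, regions) {
  reg <- regions$regions
  n <- length(lat)
  out <- integer(n)
  for (i in seq_len(n)) {
    d <- great_circle_km(lat[i], lon[i], reg$medoid_lat, reg$medoid_lon)
    # ties (to within numerical noise) break to the lower region id
    out[i] <- min(reg$region_id[d <= min(d) + 1e-9])
  }
  out
}

#' Long-format estimate table for network construction
#'
#' Combines refined complete tracks, their segmentations, and a
#' regionalization into one row per stationary estimate with its season
#' label and region id. Partial and flagged tracks are excluded: the
#' network reflects complete migrations only.
#'
#' @param refined_list list of `flyway_refined` objects.
#' @param regions a `flyway_regions` object.
#' @param thresholds a [flyway_thresholds()] object.
#' @return data.frame with `bird_id`, `subspecies`, `lat`, `lon`,
#'   `arrival`, `departure`, `label`, `region_id`.
#' @export
network_estimate_table <- function(refined_list, regions,
                                   thresholds = flyway_thresholds()) {
  rows <- lapply(refined_list, function(rf) {
    if (!rf$track$complete || rf$flagged) return(NULL)
    seg <- segment_track(rf, thresholds)
    est <- rf$track$estimates
    if (!nrow(est)) return(NULL)
    data.frame(bird_id = rf$track$bird_id,
               subspecies = rf$track$subspecies,
               lat = est$lat, lon = est$lon,
               arrival = est$arrival, departure = est$departure,
               label = seg$labels,
               region_id = assign_regions(est$lat, est$lon, regions),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subspecies complete-track denominators
#'
#' @param estimate_table data.frame from [network_estimate_table()].
#' @return named integer vector, birds per subspecies.
#' @export
subspecies_denominators <- function(estimate_table) {
  tab <- tapply(estimate_table$bird_id, estimate_table$subspecies,
                function(v) length(unique(v)))
  setNames(as.integer(tab), names(tab))
}

#' Build the migratory network for one season
#'
#' For every complete track, the season's region sequence (time order,
#' consecutive duplicates collapsed) contributes each visited region once
#' to the node weights and each consecutive ordered region pair once to
#' the directed edge weights. Weights are proportions of the
#' per-subspecies complete-track denominators. Repeat visits within the
#' season count once, and a repeated region never yields a self-edge.
#'
#' @param estimate_table data.frame from [network_estimate_table()].
#' @param season one of `"south"`, `"winter"`, `"north"`.
#' @param denominators optional named vector overriding
#'   [subspecies_denominators()].
#' @return object of class `migratory_network`: list with `season`,
#'   `nodes` (`region_id`, `subspecies`, `n`, `proportion`), `edges`
#'   (`from`, `to`, `subspecies`, `n`, `proportion`), `denominators`.
#' @export
build_season_network <- function(estimate_table, season,
                                 denominators = NULL) {
  if (!season %in% c("south", "winter", "north"))
    stop("unknown season: ", season, call. = FALSE)
  if (is.null(denominators))
    denominators <- subspecies_denominators(estimate_table)
  et <- estimate_table[estimate_table$label == season, , drop = FALSE]
  et <- et[order(et$bird_id, et$arrival), , drop = FALSE]
  node_rows <- list(); edge_rows <- list()
  for (b in unique(et$bird_id)) {
    sub <- et[et$bird_id == b, , drop = FALSE]
    seq_r <- rle(sub$region_id)$values  # collapse consecutive duplicates
    ssp <- sub$subspecies[1]
    for (r in unique(seq_r))
      node_rows[[length(node_rows) + 1]] <-
        data.frame(region_id = r, subspecies = ssp)
    if (length(seq_r) > 1) {
      pairs <- unique(cbind(seq_r[-length(seq_r)], seq_r[-1]))
      for (i in seq_len(nrow(pairs)))
        edge_rows[[length(edge_rows) + 1]] <-
          data.frame(from = pairs[i, 1], to = pairs[i, 2],
                     subspecies = ssp)
    }
  }
  count_up <- function(rows, keys) {
    if (!length(rows)) {
      out <- data.frame(matrix(nrow = 0, ncol = length(keys) + 2))
      names(out) <- c(keys, "n", "proportion")
      return(out)
    }
    df <- do.call(rbind, rows)
    agg <- aggregate(list(n = rep(1L, nrow(df))), by = df[keys], FUN = sum)
    agg$proportion <- agg$n / as.numeric(denominators[agg$subspecies])
    agg[do.call(order, agg[keys]), , drop = FALSE]
  }
  nodes <- count_up(node_rows, c("region_id", "subspecies"))
  edges <- count_up(edge_rows, c("from", "to", "subspecies"))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(season = season, nodes = nodes, edges = edges,
                 denominators = denominators),
            class = "migratory_network")
}

#' @export
print.migratory_network <- function(x, ...) {
  cat(sprintf("<migratory_network> season %s: %d node weights, %d edge weights; n = %s\n",
              x$season, nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s %d", names(x$denominators), x$denominators),
                    collapse = ", ")))
  invisible(x)
}

#' Daily occupancy profile
#'
#' The proportion of each subspecies present in each flyway region on each
#' leap-normalized ordinal day (1-365, independent of year). A bird
#' occupies a region on every day from the arrival day through the
#' departure day, inclusive, of an estimate assigned there; days in
#' transit count toward no region, and when a bird leaves one region and
#' reaches the next within the same ordinal day, the day counts toward
#' the earlier stop only (so a bird is never in two places at once).
#' Intervals wrap correctly across the year boundary.
#'
#' @param estimate_table data.frame from [network_estimate_table()].
#' @param denominators optional named vector overriding
#'   [subspecies_denominators()].
#' @return data.frame with `region_id`, `subspecies`, `day`, `n`,
#'   `proportion` (only days with nonzero occupancy are listed).
#' @export
daily_occupancy <- function(estimate_table, denominators = NULL) {
  if (is.null(denominators))
    denominators <- subspecies_denominators(estimate_table)
  estimate_table <- estimate_table[order(estimate_table$bird_id,
                                         estimate_table$arrival), ,
                                   drop = FALSE]
  rows <- lapply(seq_len(nrow(estimate_table)), function(i) {
    r <- estimate_table[i, ]
    d1 <- ordinal_day(r$arrival); d2 <- ordinal_day(r$departure)
    span <- as.numeric(difftime(r$departure, r$arrival, units = "days"))
    days <- if (span >= 364) 1:365
    else if (d2 >= d1) d1:d2
    else c(d1:365, 1:d2)  # wraps the year boundary
    data.frame(bird_id = r$bird_id, subspecies = r$subspecies,
               region_id = r$region_id, day = days,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # one bird counts once per day: a same-day region change credits the
  # earlier stop
  df <- df[!duplicated(df[c("bird_id", "day")]), , drop = FALSE]
  agg <- aggregate(list(n = rep(1L, nrow(df))),
                   by = df[c("region_id", "subspecies", "day")], FUN = sum)
  agg$proportion <- agg$n / as.numeric(denominators[agg$subspecies])
  agg <- agg[order(agg$region_id, agg$subspecies, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Region-use counts for contingency testing
#'
#' Counts, per region x subspecies x season, how many complete-track
#' individuals used the region and how many did not, ready to enter 2x2
#' Fisher tests.
#'
#' @param estimate_table data.frame from [network_estimate_table()].
#' @param season season label to restrict to, or `NULL` for any season.
#' @param denominators optional named vector.
#' @return data.frame with `region_id`, `subspecies`, `used`, `not_used`.
#' @export
summarize_region_use <- function(estimate_table, season = NULL,
                                 denominators = NULL) {
  if (is.null(denominators))
    denominators <- subspecies_denominators(estimate_table)
  et <- if (is.null(season)) estimate_table
  else estimate_table[estimate_table$label == season, , drop = FALSE]
  regions <- sort(unique(estimate_table$region_id))
  ssp <- names(denominators)
  grid <- expand.grid(region_id = regions, subspecies = ssp,
                      stringsAsFactors = FALSE)
  grid$used <- mapply(function(r, s) {
    length(unique(et$bird_id[et$region_id == r & et$subspecies == s]))
  }, grid$region_id, grid$subspecies)
  grid$not_used <- as.integer(denominators[grid$subspecies]) - grid$used
  grid
}
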