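# Reading and writing stationary-estimate tables and network GeoJSON.
#
# Canonical interchange is CSV (UTF-8, RFC 4180). One row per stationary
# estimate; one track per bird. Timestamps are ISO 8601 UTC; date-only
# values are coerced to midnight UTC. Coordinates are decimal degrees,
# latitude first in column naming.

# Column vocabulary accepted by the reader, canonical name first. The
# aliases cover the column-name dialect of deposited geolocator
# stationary-estimate supplements; the mapping lives here and nowhere else.
s1_column_aliases <- list(
  bird_id      = c("bird_id", "bird", "id", "individual", "bird.id", "metal"),
  subspecies   = c("subspecies", "ssp", "taxon"),
  site_id      = c("site_id", "site", "capture_site", "field_site"),
  breeding_lat = c("breeding_lat", "breed_lat", "capture_lat",
                   "breeding_latitude", "site_lat"),
  breeding_lon = c("breeding_lon", "breed_lon", "capture_lon",
                   "breeding_longitude", "site_lon"),
  lat          = c("lat", "latitude", "stop_lat", "median_lat"),
  lon          = c("lon", "long", "longitude", "stop_lon", "median_lon"),
  arrival      = c("arrival", "arrive", "arrival_date", "start", "arrival_utc"),
  departure    = c("departure", "depart", "departure_date", "end",
                   "departure_utc"),
  complete     = c("complete", "complete_track", "track_complete")
)

SUBSPECIES_LEVELS <- c("actites", "arcticola", "kistchinski", "sakhalina")

parse_utc <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  iso <- grepl("[T ]", x)
  if (any(iso))
    out[iso] <- as.POSIXct(x[iso], tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%dT%H:%M",
                                          "%Y-%m-%d %H:%M"))
  if (any(!iso)) {
    d <- as.Date(x[!iso], optional = TRUE, format = "%Y-%m-%d")
    out[!iso] <- as.POSIXct(d, tz = "UTC")  # date-only -> midnight UTC
  }
  out
}

#' Construct a single bird's track
#'
#' @param bird_id identifier, used as-is.
#' @param subspecies one of `"actites"`, `"arcticola"`, `"kistchinski"`,
#'   `"sakhalina"` (case-insensitive).
#' @param breeding_lat,breeding_lon breeding (capture) site, decimal degrees.
#' @param estimates data.frame with columns `lat`, `lon`, `arrival`,
#'   `departure` (POSIXct, UTC). Sorted by arrival; intervals must not
#'   overlap.
#' @param complete logical; `TRUE` when the track spans south departure
#'   through return to the breeding site.
#' @param site_id optional capture-site identifier.
#' @param tracking_year optional integer year the track started.
#' @return object of class `flyway_track`.
#' @export
flyway_track <- function(bird_id, subspecies, breeding_lat, breeding_lon,
                         estimates, complete = TRUE, site_id = NA_character_,
                         tracking_year = NA_integer_) {
  subspecies <- match.arg(tolower(as.character(subspecies)),
                          SUBSPECIES_LEVELS)
  check_latlon(breeding_lat, breeding_lon, "breeding site")
  estimates <- validate_estimates(estimates, bird_id)
  structure(list(bird_id = as.character(bird_id),
                 subspecies = subspecies,
                 site_id = as.character(site_id),
                 breeding_lat = as.numeric(breeding_lat),
                 breeding_lon = normalize_lon(as.numeric(breeding_lon)),
                 tracking_year = as.integer(tracking_year),
                 estimates = estimates,
                 complete = isTRUE(complete)),
            class = "flyway_track")
}

validate_estimates <- function(est, bird_id = "?") {
  need <- c("lat", "lon", "arrival", "departure")
  miss <- setdiff(need, names(est))
  if (length(miss))
    stop("track ", bird_id, ": estimates missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  est <- as.data.frame(est)[need]
  if (nrow(est) == 0) {
    est$lat <- numeric(0); est$lon <- numeric(0)
    return(est)
  }
  check_latlon(est$lat, est$lon, paste0("track ", bird_id))
  est$lon <- normalize_lon(est$lon)
  if (any(est$departure < est$arrival))
    stop("track ", bird_id, ": departure before arrival", call. = FALSE)
  est <- est[order(est$arrival), , drop = FALSE]
  rownames(est) <- NULL
  if (nrow(est) > 1 &&
      any(est$arrival[-1] < est$departure[-nrow(est)] - 1e-6))
    stop("track ", bird_id, ": overlapping stationary intervals",
         call. = FALSE)
  est
}

#' Duration of stationary estimates in days
#' @param estimates data.frame with `arrival`, `departure` POSIXct columns.
#' @return numeric vector of days.
#' @export
estimate_duration_days <- function(estimates) {
  as.numeric(difftime(estimates$departure, estimates$arrival, units = "days"))
}

#' @export
print.flyway_track <- function(x, ...) {
  cat(sprintf("<flyway_track> %s (%s), %d stationary estimates, %s\n",
              x$bird_id, x$subspecies, nrow(x$estimates),
              if (x$complete) "complete" else "partial"))
  invisible(x)
}

#' Read a stationary-estimate table into tracks
#'
#' Expects one row per stationary estimate with (aliases accepted) columns
#' `bird_id`, `subspecies`, `breeding_lat`, `breeding_lon`, `lat`, `lon`,
#' `arrival`, `departure`, `complete`, and optional `site_id`. Rows may be
#' in any order; estimates are sorted by arrival within each bird.
#' Problems are reported per row so one bad record cannot silently drop a
#' bird.
#'
#' @param path CSV file path or connection.
#' @return list of [flyway_track()] objects, named by `bird_id`.
#' @export
read_stationary_tracks <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  # resolve aliases
  col <- vapply(names(s1_column_aliases), function(cn) {
    hit <- intersect(s1_column_aliases[[cn]], names(raw))
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  required <- setdiff(names(s1_column_aliases), "site_id")
  miss <- required[is.na(col[required])]
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data.frame(bird_id = as.character(raw[[col["bird_id"]]]),
                   subspecies = tolower(trimws(raw[[col["subspecies"]]])),
                   site_id = if (!is.na(col["site_id"]))
                     as.character(raw[[col["site_id"]]]) else NA_character_,
                   breeding_lat = as.numeric(raw[[col["breeding_lat"]]]),
                   breeding_lon = as.numeric(raw[[col["breeding_lon"]]]),
                   lat = as.numeric(raw[[col["lat"]]]),
                   lon = as.numeric(raw[[col["lon"]]]),
                   stringsAsFactors = FALSE)
  df$arrival <- parse_utc(raw[[col["arrival"]]])
  df$departure <- parse_utc(raw[[col["departure"]]])
  df$complete <- as.logical(raw[[col["complete"]]])

  problems <- character(0)
  bad_row <- function(i, msg) sprintf("row %d: %s", i, msg)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$arrival[i]) || is.na(df$departure[i]))
      problems <- c(problems, bad_row(i, "unparseable timestamp"))
    else if (df$departure[i] < df$arrival[i])
      problems <- c(problems, bad_row(i, "departure before arrival"))
    if (!df$subspecies[i] %in% SUBSPECIES_LEVELS)
      problems <- c(problems,
                    bad_row(i, paste0("unknown subspecies '",
                                      df$subspecies[i], "'")))
  }
  if (length(problems))
    stop("invalid stationary-estimate records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  tracks <- lapply(split(df, df$bird_id), function(b) {
    flyway_track(bird_id = b$bird_id[1],
                 subspecies = b$subspecies[1],
                 site_id = b$site_id[1],
                 breeding_lat = b$breeding_lat[1],
                 breeding_lon = b$breeding_lon[1],
                 estimates = b[c("lat", "lon", "arrival", "departure")],
                 complete = b$complete[1])
  })
  tracks[order(names(tracks))]
}

#' Write tracks back to the canonical CSV schema
#'
#' @param tracks list of `flyway_track` objects.
#' @param path output CSV path.
#' @export
write_stationary_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    if (nrow(tr$estimates) == 0) return(NULL)
    data.frame(bird_id = tr$bird_id,
               subspecies = tr$subspecies,
               site_id = tr$site_id,
               breeding_lat = tr$breeding_lat,
               breeding_lon = tr$breeding_lon,
               lat = tr$estimates$lat,
               lon = tr$estimates$lon,
               arrival = format(tr$estimates$arrival,
                                "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               departure = format(tr$estimates$departure,
                                  "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               complete = tr$complete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Built-in registry of the eight Beringia deployment sites
#'
#' Coordinates, subspecies, and site letters of the eight Arctic and
#' sub-Arctic field sites where the geolocators behind this pipeline were
#' deployed.
#'
#' @return data.frame with columns `site_id`, `name`, `lat`, `lon`,
#'   `subspecies`.
#' @export
site_registry <- function() {
  data.frame(
    site_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    name = c("Utqiagvik, Alaska", "Ikpikpuk River, Alaska",
             "Canning River, Alaska", "Chaun Delta, Russia",
             "Belyaka Spit, Russia", "Meinypilgyno, Russia",
             "Cape Pogodny, Russia", "Chaivo Bay, Russia"),
    lat = c(71.2652, 70.5525, 70.1180, 68.7750,
            67.0647, 62.5833, 56.2645, 52.5000),
    lon = c(-156.6359, -154.7309, -145.8506, 170.5495,
            -174.5000, 177.0300, 162.5815, 143.2833),
    subspecies = c("arcticola", "arcticola", "arcticola", "sakhalina",
                   "sakhalina", "sakhalina", "kistchinski", "actites"),
    stringsAsFactors = FALSE)
}

#' Read a deployment table and summarize tag bookkeeping
#'
#' The deployment table has one row per site x deployment-year with columns
#' `site_id`, `subspecies`, `year`, `n_deployed`, `n_complete`, `n_partial`
#' (complete/partial = recovered tags with complete/partial migration
#' tracks). A transcription of the study's deployment table ships with the
#' package (`system.file("extdata", "deployments.csv", package =
#' "flywaynet")`).
#'
#' @param path CSV path; default is the shipped transcription.
#' @return the deployment data.frame, invisibly used by
#'   [deployment_summary()].
#' @export
read_deployment_table <- function(path = system.file("extdata",
                                                     "deployments.csv",
                                                     package = "flywaynet")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "subspecies", "year", "n_deployed", "n_complete",
            "n_partial")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("deployment table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Ingest summary of deployments and recovered tracks
#'
#' @param deployments data.frame from [read_deployment_table()].
#' @return list with `total_deployed`, `complete_tracks`, `partial_tracks`,
#'   and a per-subspecies breakdown data.frame.
#' @export
deployment_summary <- function(deployments = read_deployment_table()) {
  by_ssp <- aggregate(deployments[c("n_deployed", "n_complete", "n_partial")],
                      by = list(subspecies = deployments$subspecies), sum)
  list(total_deployed = sum(deployments$n_deployed),
       complete_tracks = sum(deployments$n_complete),
       partial_tracks = sum(deployments$n_partial),
       by_subspecies = by_ssp)
}

# ---- GeoJSON export of a season network ------------------------------------

#' Write a migratory network as GeoJSON
#'
#' Nodes become Point features at region medoids carrying per-subspecies
#' proportions; edges become two-point LineString features. The result
#' renders directly in standard GeoJSON viewers.
#'
#' @param network a `migratory_network` from [build_season_network()].
#' @param regions a `flyway_regions` object from [regionalize()].
#' @param path output path.
#' @export
write_network_geojson <- function(network, regions, path) {
  reg <- regions$regions
  medoid <- function(id) {
    i <- match(id, reg$region_id)
    if (is.na(i)) stop("unknown region id: ", id, call. = FALSE)
    c(reg$medoid_lon[i], reg$medoid_lat[i])
  }
  feats <- list()
  if (nrow(network$nodes)) {
    for (id in unique(network$nodes$region_id)) {
      sub <- network$nodes[network$nodes$region_id == id, , drop = FALSE]
      props <- c(list(region_id = id, season = network$season,
                      feature = "node"),
                 as.list(setNames(sub$proportion, sub$subspecies)))
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = medoid(id)),
        properties = props)
    }
  }
  if (nrow(network$edges)) {
    key <- paste(network$edges$from, network$edges$to)
    for (k in unique(key)) {
      sub <- network$edges[key == k, , drop = FALSE]
      props <- c(list(from = sub$from[1], to = sub$to[1],
                      season = network$season, feature = "edge"),
                 as.list(setNames(sub$proportion, sub$subspecies)))
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        geometry = list(type = "LineString",
                        coordinates = list(medoid(sub$from[1]),
                                           medoid(sub$to[1]))),
        properties = props)
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a network GeoJSON file
#'
#' Inverse of [write_network_geojson()] for round-trip checks and for
#' downstream consumers that want the weights without re-running the
#' pipeline.
#'
#' @param path GeoJSON path.
#' @return list with data.frames `nodes` (`region_id`, `subspecies`,
#'   `proportion`) and `edges` (`from`, `to`, `subspecies`, `proportion`)
#'   and the `season` string (NA for an empty collection).
#' @export
read_network_geojson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- list(); edges <- list(); season <- NA_character_
  meta <- c("region_id", "season", "feature", "from", "to")
  for (f in doc$features) {
    p <- f$properties
    season <- p$season
    ssp <- setdiff(names(p), meta)
    if (identical(p$feature, "node")) {
      nodes[[length(nodes) + 1]] <-
        data.frame(region_id = as.integer(p$region_id), subspecies = ssp,
                   proportion = as.numeric(unlist(p[ssp])),
                   stringsAsFactors = FALSE)
    } else {
      edges[[length(edges) + 1]] <-
        data.frame(from = as.integer(p$from), to = as.integer(p$to),
                   subspecies = ssp,
                   proportion = as.numeric(unlist(p[ssp])),
                   stringsAsFactors = FALSE)
    }
  }
  list(season = season,
       nodes = if (length(nodes)) do.call(rbind, nodes) else
         data.frame(region_id = integer(0), subspecies = character(0),
                    proportion = numeric(0)),
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(from = integer(0), to = integer(0),
                    subspecies = character(0), proportion = numeric(0)))
}
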