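# Small constructors for hand-built fixtures. Days count from a fixed
# origin; estimates are built from (lat, lon, arrival day, departure day).

day0 <- as.POSIXct("2018-01-01", tz = "UTC")

d2t <- function(day) day0 + day * 86400

mk_est <- function(lat, lon, arr_day, dep_day) {
  data.frame(lat = lat, lon = lon,
             arrival = d2t(arr_day), departure = d2t(dep_day))
}

mk_track <- function(est, breeding_lat = 70, breeding_lon = -150,
                     bird_id = "t1", subspecies = "arcticola",
                     complete = TRUE) {
  flyway_track(bird_id = bird_id, subspecies = subspecies,
               breeding_lat = breeding_lat, breeding_lon = breeding_lon,
               estimates = est, complete = complete)
}

as_refined <- function(track) {
  structure(list(track = track, provenance = list(), flagged = FALSE),
            class = "flyway_refined")
}

# degrees of longitude on the equator giving a target km distance
eq_deg <- function(km) km / (6371 * pi / 180)

# point exactly `km` due south of (lat, lon): meridional displacement is an
# exact great-circle distance
move_north <- function(lat, lon, km) c(lat - km / (6371 * pi / 180), lon)

# total days covered by the union of [arrival, departure] intervals
union_days <- function(est) {
  if (!nrow(est)) return(0)
  a <- as.numeric(est$arrival); d <- as.numeric(est$departure)
  o <- order(a); a <- a[o]; d <- d[o]
  tot <- 0; cur_a <- a[1]; cur_d <- d[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_d) { tot <- tot + (cur_d - cur_a); cur_a <- a[i]; cur_d <- d[i] }
    else cur_d <- max(cur_d, d[i])
  }
  (tot + (cur_d - cur_a)) / 86400
}
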