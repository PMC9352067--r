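# Spherical geometry primitives. All distances use a sphere of radius
# 6371 km; the coarse thresholds elsewhere in the pipeline (250-700 km)
# make sub-0.5% ellipsoidal corrections immaterial.

#' Default Earth radius (km)
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0

#' Normalize longitudes to (-180, 180]
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector with each value wrapped into `(-180, 180]`.
#' @export
normalize_lon <- function(lon) {
  l <- (lon + 180) %% 360
  ifelse(l == 0, 180, l - 180)
}

check_latlon <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop(what, ": non-finite coordinates", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop(what, ": latitude outside [-90, 90]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance (haversine) in kilometers
#'
#' Distance between points on a sphere. Vectorized over coordinates;
#' vectors are recycled as in arithmetic.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees.
#' @param radius_km sphere radius, kilometers.
#' @return numeric vector of distances in kilometers.
#' @examples
#' great_circle_km(0, 0, 0, 90)  # quarter great circle, ~10007.5 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2,
                            radius_km = EARTH_RADIUS_KM) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  stopifnot(radius_km > 0)
  n <- max(length(lat1), length(lat2))
  p1 <- cbind(rep_len(normalize_lon(lon1), n), rep_len(lat1, n))
  p2 <- cbind(rep_len(normalize_lon(lon2), n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = radius_km))
}

#' Initial great-circle bearing, degrees clockwise from north
#'
#' @inheritParams great_circle_km
#' @return bearing(s) in `[0, 360)`. Coincident points are an error: the
#'   bearing is undefined there.
#' @export
initial_bearing_deg <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  n <- max(length(lat1), length(lat2))
  lo1 <- rep_len(normalize_lon(lon1), n); la1 <- rep_len(lat1, n)
  lo2 <- rep_len(normalize_lon(lon2), n); la2 <- rep_len(lat2, n)
  if (any(la1 == la2 & lo1 == lo2))
    stop("bearing undefined for coincident points", call. = FALSE)
  b <- geosphere::bearing(cbind(lo1, la1), cbind(lo2, la2),
                          a = EARTH_RADIUS_KM * 1000, f = 0)
  as.numeric(b %% 360)
}

#' Turning angle at a track vertex
#'
#' Interior angle at `vertex` between the great-circle directions toward the
#' previous and the next stop: 180 means straight-through travel, 0 an exact
#' out-and-back reversal. Used by the refinement rules to flag erratic
#' geolocator estimates.
#'
#' @param lat_prev,lon_prev previous stop.
#' @param lat_v,lon_v the vertex stop.
#' @param lat_next,lon_next next stop.
#' @return angle(s) in degrees, `[0, 180]`.
#' @export
turning_angle_deg <- function(lat_prev, lon_prev, lat_v, lon_v,
                              lat_next, lon_next) {
  b1 <- initial_bearing_deg(lat_v, lon_v, lat_prev, lon_prev)
  b2 <- initial_bearing_deg(lat_v, lon_v, lat_next, lon_next)
  d <- (b1 - b2 + 180) %% 360 - 180
  abs(d)
}

#' Spherical mean of locations
#'
#' Mean of unit vectors on the sphere (the chord centroid projected back to
#' the surface), optionally weighted. Safe across the antimeridian, unlike a
#' naive mean of longitudes; the flyway this package was built for crosses
#' the 180 degree meridian.
#'
#' @param lat,lon numeric vectors, decimal degrees.
#' @param weights optional non-negative weights, not all zero.
#' @return named numeric vector `c(lat = , lon = )`.
#' @export
mean_location <- function(lat, lon, weights = NULL) {
  check_latlon(lat, lon)
  n <- length(lat)
  stopifnot(n >= 1, length(lon) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  la <- lat * pi / 180; lo <- normalize_lon(lon) * pi / 180
  w <- weights / sum(weights)
  x <- sum(w * cos(la) * cos(lo))
  y <- sum(w * cos(la) * sin(lo))
  z <- sum(w * sin(la))
  r <- sqrt(x^2 + y^2 + z^2)
  if (r < 1e-9)
    stop("mean location undefined: input points are (near-)antipodal",
         call. = FALSE)
  c(lat = asin(z / r) * 180 / pi,
    lon = normalize_lon(atan2(y, x) * 180 / pi))
}
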