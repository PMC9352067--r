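# Diameter-constrained k-medoid regionalization of stationary estimates
# into flyway regions.

#' Partitioning around medoids on the great-circle metric
#'
#' Classic deterministic PAM (BUILD initialization, then SWAP until no
#' single medoid/non-medoid exchange reduces the total cost), run on the
#' great-circle distance matrix of the points. Medoids are actual points.
#'
#' @param lat,lon point coordinates, decimal degrees.
#' @param k number of clusters, `1 <= k <= n`.
#' @return list with `medoids` (indices into the input), `assignment`
#'   (medoid index for every point), and `total_cost` (sum of
#'   point-to-medoid distances, km).
#' @export
flyway_pam <- function(lat, lon, k) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (k > n) stop("k cannot exceed the number of points", call. = FALSE)
  D <- great_circle_matrix(lat, lon)
  if (k == n) {
    return(list(medoids = seq_len(n), assignment = seq_len(n),
                total_cost = 0))
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      keep.diss = FALSE)
  medoids <- as.integer(fit$id.med)
  assignment <- medoids[fit$clustering]
  list(medoids = medoids,
       assignment = assignment,
       total_cost = sum(D[cbind(seq_len(n), assignment)]))
}

great_circle_matrix <- function(lat, lon) {
  p <- cbind(normalize_lon(lon), lat)
  D <- geosphere::distm(p, fun = geosphere::distHaversine) / 1000 *
    (EARTH_RADIUS_KM / 6378.137)
  # distm has no radius argument; rescale from its default sphere
  dimnames(D) <- NULL
  D
}

cluster_diameter <- function(D, members, method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(members) < 2) return(0)
  sub <- D[members, members, drop = FALSE]
  v <- sub[upper.tri(sub)]
  if (method == "max") max(v) else mean(v)
}

#' Regionalize stationary estimates into flyway regions
#'
#' Searches k = 1, 2, 3, ... and keeps the first PAM solution whose median
#' cluster diameter (maximum pairwise member distance by default) falls
#' below `region_median_diam_km` -- the coarsest regionalization
#' consistent with the rule. k = n always satisfies it, so the search
#' terminates. Regions are numbered by medoid latitude, then longitude,
#' for stable ids.
#'
#' @param points data.frame with columns `lat`, `lon` and optionally
#'   `bird_id`, `label` (annual-cycle period of each estimate).
#' @param thresholds a [flyway_thresholds()] object.
#' @param diameter `"max"` (the standard cluster diameter) or `"mean"`
#'   (mean pairwise member distance).
#' @return object of class `flyway_regions`: list with `regions`
#'   (data.frame `region_id`, `medoid_lat`, `medoid_lon`, `n_members`,
#'   `diameter_km`), `assignment` (region id per input point), `k`,
#'   `median_diameter_km`, and the input `points` with assignment column
#'   added.
#' @export
regionalize <- function(points, thresholds = flyway_thresholds(),
                        diameter = c("max", "mean")) {
  diameter <- match.arg(diameter)
  stopifnot(nrow(points) >= 1)
  n <- nrow(points)
  D <- great_circle_matrix(points$lat, points$lon)
  for (k in seq_len(n)) {
    fit <- if (k == n) {
      list(medoids = seq_len(n), assignment = seq_len(n),
           total_cost = 0)
    } else {
      pam_fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                              keep.diss = FALSE)
      med <- as.integer(pam_fit$id.med)
      list(medoids = med, assignment = med[pam_fit$clustering],
           total_cost = sum(D[cbind(seq_len(n),
                                    med[pam_fit$clustering])]))
    }
    diams <- vapply(fit$medoids, function(m) {
      cluster_diameter(D, which(fit$assignment == m), diameter)
    }, numeric(1))
    if (median(diams) < thresholds$region_median_diam_km) break
  }
  # stable ids: ascending medoid latitude, then longitude
  ord <- order(points$lat[fit$medoids], points$lon[fit$medoids])
  medoids <- fit$medoids[ord]
  region_of_medoid <- setNames(seq_along(medoids), medoids)
  assignment <- as.integer(region_of_medoid[as.character(fit$assignment)])
  regions <- data.frame(
    region_id = seq_along(medoids),
    medoid_lat = points$lat[medoids],
    medoid_lon = points$lon[medoids],
    n_members = as.integer(table(factor(assignment,
                                        seq_along(medoids)))),
    diameter_km = vapply(seq_along(medoids), function(r) {
      cluster_diameter(D, which(assignment == r), diameter)
    }, numeric(1)))
  pts <- points
  pts$region_id <- assignment
  structure(list(regions = regions, assignment = assignment, k = length(medoids),
                 median_diameter_km = median(regions$diameter_km),
                 points = pts),
            class = "flyway_regions")
}

#' @export
print.flyway_regions <- function(x, ...) {
  cat(sprintf("<flyway_regions> %d regions over %d estimates (median diameter %.0f km)\n",
              x$k, nrow(x$points), x$median_diameter_km))
  print(x$regions)
  invisible(x)
}

#' Classify seasonal usage of flyway regions
#'
#' A region's season usage contains a season iff at least one estimate
#' carrying that season label falls in it. Regions used during south or
#' north migration but never in winter are migration-only regions; any
#' region with a winter member is a winter region.
#'
#' @param regions a `flyway_regions` whose `points` carry a `label` column
#'   (from [segment_track()]).
#' @return the `flyway_regions` object with `seasons`, `migration_only`,
#'   and `winter_region` columns added to `$regions`.
#' @export
classify_usage <- function(regions) {
  stopifnot(inherits(regions, "flyway_regions"),
            "label" %in% names(regions$points))
  pts <- regions$points
  usage <- vapply(regions$regions$region_id, function(r) {
    labs <- unique(pts$label[pts$region_id == r])
    paste(sort(intersect(c("south", "winter", "north"), labs)),
          collapse = "+")
  }, character(1))
  regions$regions$seasons <- usage
  has <- function(s) grepl(s, usage, fixed = TRUE)
  regions$regions$winter_region <- has("winter")
  regions$regions$migration_only <- !has("winter") &
    (has("south") | has("north"))
  regions
}
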