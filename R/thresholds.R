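#' Pipeline thresholds
#'
#' The rule constants used throughout refinement, segmentation,
#' regionalization, and the comparison statistics. Defaults follow the
#' field conventions for geolocator-tracked Dunlin on the East
#' Asian-Australasian Flyway:
#'
#' * `merge_km` (250): sequential stationary estimates closer than this are
#'   merged -- a conservative buffer for geolocator spatial resolution.
#' * `breed_buffer_km` (250): estimates before the bird first travels this
#'   far from its breeding site are discarded; an estimate this close to the
#'   breeding site on return ends north migration.
#' * `polar_lat_deg` (66.7): solar geolocation fails under continuous
#'   daylight; estimates before the bird first moves south of this latitude
#'   are discarded.
#' * `winter_lat_deg` (45.5) and `winter_min_days` (42): a stop south of
#'   45.5 degrees N lasting at least 42 days opens (and, for the last such
#'   stop, closes) the winter period.
#' * `turn_min_deg` (60): interior stops subtending a turning angle below
#'   this are treated as track artifacts and removed.
#' * `travel_kmh` (58): assumed flight speed for back/forward-calculating
#'   departure from and arrival at the breeding site.
#' * `region_median_diam_km` (700): flyway regionalization picks the
#'   smallest number of clusters whose median diameter is below this,
#'   matching typical geolocator location error.
#' * `min_stationary_days` (2): minimum stationary period in the upstream
#'   location summaries.
#' * `fisher_min_n` (25) and `wilcoxon_min_n` (5): minimum per-group sample
#'   sizes for the pairwise region-use and migration-parameter tests.
#'
#' @param merge_km,breed_buffer_km,polar_lat_deg,winter_lat_deg,winter_min_days,turn_min_deg,travel_kmh,region_median_diam_km,min_stationary_days,fisher_min_n,wilcoxon_min_n
#'   numeric scalars, all strictly positive.
#' @return an object of class `flyway_thresholds` (a validated named list).
#' @export
flyway_thresholds <- function(merge_km = 250,
                              breed_buffer_km = 250,
                              polar_lat_deg = 66.7,
                              winter_lat_deg = 45.5,
                              winter_min_days = 42,
                              turn_min_deg = 60,
                              travel_kmh = 58,
                              region_median_diam_km = 700,
                              min_stationary_days = 2,
                              fisher_min_n = 25,
                              wilcoxon_min_n = 5) {
  thr <- list(merge_km = merge_km,
              breed_buffer_km = breed_buffer_km,
              polar_lat_deg = polar_lat_deg,
              winter_lat_deg = winter_lat_deg,
              winter_min_days = winter_min_days,
              turn_min_deg = turn_min_deg,
              travel_kmh = travel_kmh,
              region_median_diam_km = region_median_diam_km,
              min_stationary_days = min_stationary_days,
              fisher_min_n = fisher_min_n,
              wilcoxon_min_n = wilcoxon_min_n)
  for (nm in names(thr)) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("threshold '", nm, "' must be a positive finite scalar",
           call. = FALSE)
  }
  structure(thr, class = "flyway_thresholds")
}

#' @export
print.flyway_thresholds <- function(x, ...) {
  cat("Flyway pipeline thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' A single JSON document with optional sections `thresholds`, `simulation`,
#' and `run`. Omitted threshold keys take their defaults; unknown keys are
#' rejected so typos cannot silently revert a value to its default.
#'
#' @param path path to a JSON file.
#' @return list with elements `thresholds` (a [flyway_thresholds()] object),
#'   `simulation` (named list of generator overrides, possibly empty), and
#'   `run` (named list of run options, possibly empty).
#' @export
read_flyway_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc)) doc <- list()
  known <- c("thresholds", "simulation", "run")
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  thr_args <- as.list(doc$thresholds %||% list())
  bad <- setdiff(names(thr_args), names(formals(flyway_thresholds)))
  if (length(bad))
    stop("unknown threshold key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(thresholds = do.call(flyway_thresholds, thr_args),
       simulation = as.list(doc$simulation %||% list()),
       run = as.list(doc$run %||% list()))
}

#' Write a pipeline configuration file
#'
#' @param config list as returned by [read_flyway_config()].
#' @param path output path.
#' @export
write_flyway_config <- function(config, path) {
  doc <- list(thresholds = unclass(config$thresholds),
              simulation = config$simulation %||% list(),
              run = config$run %||% list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
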