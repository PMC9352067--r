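# End-to-end orchestration: simulate or ingest -> refine -> segment ->
# parameters -> regionalize -> networks -> occupancy -> statistics, with
# deterministic artifacts and a run manifest.

#' Run the full migratory-network pipeline
#'
#' Executes every stage in order and writes the standard artifacts to
#' `outdir`: refined tracks (`tracks_refined.csv`), the raw input when
#' simulated (`tracks_raw.csv`) plus a truth table (`truth.csv`), the
#' per-bird segmentation (`segmentation.csv`), the per-bird x period
#' parameter table (`parameters.csv`) and its median/IQR summary with
#' per-subspecies sample sizes (`parameter_summary.csv`), the flyway
#' region table (`regions.csv`), one GeoJSON network per season
#' (`network_<season>.geojson`), the daily occupancy profile
#' (`occupancy.csv`), the statistics table (`stats.csv`), and a manifest
#' (`manifest.json`) with input/output digests. Re-running with identical
#' inputs and configuration reproduces identical digests.
#'
#' @param input path to a stationary-estimate CSV, or `NULL` to simulate.
#' @param config list as from [read_flyway_config()]; `NULL` for all
#'   defaults.
#' @param outdir output directory (created if needed).
#' @param seed integer; overrides the simulation seed.
#' @param skip_refinement set `TRUE` when ingesting already-refined
#'   estimates.
#' @param seasons seasons to build networks for.
#' @return (invisibly) a list with all in-memory stage outputs.
#' @export
run_flyway_pipeline <- function(input = NULL, config = NULL,
                                outdir = tempfile("flywaynet_run_"),
                                seed = NULL, skip_refinement = FALSE,
                                seasons = c("south", "winter", "north")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- if (!is.null(config$thresholds)) config$thresholds
  else flyway_thresholds()
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  truth <- NULL
  if (is.null(input)) {
    sim_args <- config$simulation %||% list()
    if (!is.null(seed)) sim_args$seed <- seed
    sim_cfg <- do.call(make_paper_like_config, sim_args)
    sim <- simulate_population(sim_cfg)
    tracks <- sim$tracks
    truth <- sim$truth
    write_stationary_tracks(tracks, file.path(outdir, "tracks_raw.csv"))
    write_truth_table(truth, file.path(outdir, "truth.csv"))
  } else {
    tracks <- read_stationary_tracks(input)
  }

  refined <- lapply(tracks, function(tr) {
    if (skip_refinement)
      structure(list(track = tr, provenance = list(), flagged = FALSE),
                class = "flyway_refined")
    else withCallingHandlers(refine_track(tr, thr), warning = function(w) {
      note("refine %s: %s", tr$bird_id, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  })
  write_stationary_tracks(lapply(refined, `[[`, "track"),
                          file.path(outdir, "tracks_refined.csv"))

  segs <- lapply(refined, segment_track, thresholds = thr)
  seg_df <- do.call(rbind, lapply(segs, function(s)
    data.frame(bird_id = s$bird_id, status = s$status,
               south_initiation = format(s$south_initiation, "%Y-%m-%dT%H:%M:%S"),
               winter_arrival = format(s$winter_arrival, "%Y-%m-%dT%H:%M:%S"),
               winter_end = format(s$winter_end, "%Y-%m-%dT%H:%M:%S"),
               breeding_arrival = format(s$breeding_arrival, "%Y-%m-%dT%H:%M:%S"),
               labels = paste(s$labels, collapse = ";"),
               stringsAsFactors = FALSE)))
  utils::write.csv(seg_df, file.path(outdir, "segmentation.csv"),
                   row.names = FALSE)
  for (s in segs)
    if (s$status != "complete")
      note("segmentation %s: %s", s$bird_id, s$status)

  params <- parameter_table(refined, thr)
  flat <- params[setdiff(names(params), "stop_durations")]
  utils::write.csv(flat, file.path(outdir, "parameters.csv"),
                   row.names = FALSE)
  summary_tab <- summarize_parameters(params)
  utils::write.csv(summary_tab, file.path(outdir, "parameter_summary.csv"),
                   row.names = FALSE)

  # regionalization over complete, unflagged tracks only
  usable <- Filter(function(rf) rf$track$complete && !rf$flagged, refined)
  pts <- do.call(rbind, lapply(usable, function(rf) {
    seg <- segs[[rf$track$bird_id]]
    est <- rf$track$estimates
    if (!nrow(est)) return(NULL)
    data.frame(bird_id = rf$track$bird_id, lat = est$lat, lon = est$lon,
               label = seg$labels, stringsAsFactors = FALSE)
  }))
  regions <- classify_usage(regionalize(pts, thr))
  utils::write.csv(regions$regions, file.path(outdir, "regions.csv"),
                   row.names = FALSE)

  et <- network_estimate_table(usable, regions, thr)
  denom <- subspecies_denominators(et)
  networks <- list()
  for (season in seasons) {
    networks[[season]] <- build_season_network(et, season, denom)
    write_network_geojson(networks[[season]], regions,
                          file.path(outdir,
                                    paste0("network_", season, ".geojson")))
  }
  occupancy <- daily_occupancy(et, denom)
  utils::write.csv(occupancy, file.path(outdir, "occupancy.csv"),
                   row.names = FALSE)

  stat_rows <- list()
  for (season in seasons) {
    use <- summarize_region_use(et, season, denom)
    ft <- pairwise_region_tests(use, thr, season = season)
    ft$period <- season; ft$parameter <- "region_use"
    stat_rows[[length(stat_rows) + 1]] <-
      ft[c("test", "period", "parameter", "region_id", "subspecies_1",
           "subspecies_2", "n1", "n2", "p")]
  }
  wt <- pairwise_parameter_tests(params, thr)
  if (nrow(wt)) {
    wt$region_id <- NA_integer_
    stat_rows[[length(stat_rows) + 1]] <-
      wt[c("test", "period", "parameter", "region_id", "subspecies_1",
           "subspecies_2", "n1", "n2", "p")]
  }
  stats_tab <- do.call(rbind, stat_rows)
  utils::write.csv(stats_tab, file.path(outdir, "stats.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("flywaynet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    thresholds = unclass(thr),
    input = if (is.null(input)) "simulated" else normalizePath(input),
    input_digest = if (!is.null(input))
      unname(tools::md5sum(input)) else NA,
    seed = seed,
    warnings = warnings_log,
    outputs = as.list(output_digests(outdir)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(tracks = tracks, truth = truth, refined = refined,
                 segmentations = segs, parameters = params,
                 parameter_summary = summary_tab, regions = regions,
                 estimate_table = et, networks = networks,
                 occupancy = occupancy, stats = stats_tab,
                 outdir = outdir, warnings = warnings_log))
}

output_digests <- function(outdir) {
  files <- setdiff(list.files(outdir), "manifest.json")
  d <- tools::md5sum(file.path(outdir, files))
  setNames(unname(d), files)
}

write_truth_table <- function(truth, path) {
  rows <- lapply(truth, function(tt) {
    data.frame(bird_id = tt$bird_id, subspecies = tt$subspecies,
               field = c("south_initiation", "winter_arrival",
                         "winter_end", "breeding_arrival"),
               value = format(c(tt$south_initiation, tt$winter_arrival,
                                tt$winter_end, tt$breeding_arrival),
                              "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Recompute headline summaries from a deposited stationary-estimate table
#'
#' Ingests a stationary-estimate CSV (for instance a transcription of a
#' published geolocator supplement), runs refinement, segmentation,
#' parameter estimation, and regionalization, and returns the headline
#' quantities reported in studies of this design: per-subspecies medians
#' of period duration and distance, and counts of migration-only, winter,
#' and north-migration regions.
#'
#' @param path CSV of stationary estimates in the reader's schema.
#' @param thresholds a [flyway_thresholds()] object.
#' @param skip_refinement `TRUE` if the deposited estimates are already
#'   refined.
#' @return list with `summary` (the [summarize_parameters()] table),
#'   `n_migration_only_regions`, `n_winter_regions`,
#'   `n_north_regions`, and `region_table`.
#' @export
reproduce_published_summaries <- function(path,
                                          thresholds = flyway_thresholds(),
                                          skip_refinement = FALSE) {
  out <- run_flyway_pipeline(input = path, outdir = tempfile("repro_"),
                             config = list(thresholds = thresholds),
                             skip_refinement = skip_refinement)
  reg <- out$regions$regions
  list(summary = out$parameter_summary,
       n_migration_only_regions = sum(reg$migration_only),
       n_winter_regions = sum(reg$winter_region),
       n_north_regions = sum(grepl("north", reg$seasons)),
       region_table = reg)
}
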