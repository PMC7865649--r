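# End-to-end pipelines behind the command-line front end.  Each run_*()
# function is a plain R surface; the CLI in inst/cli/tdoatrack.R is a thin
# wrapper that maps files and flags onto these calls.

.notice_once <- function(verbose) {
  if (verbose) {
    message("distance model: equirectangular flat earth ",
            "(north-south term = latitude difference); ",
            "objective: RMSE over matched lag-distance pairs")
  }
}

.write_config_snapshot <- function(out_dir, config) {
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
}

#' Localize every call in a detections file
#'
#' Reads stations and long-format detections, localizes each call over a
#' shared grid, and writes `results.csv`, `results.geojson`, `results.kml`
#' and a `run_config.json` snapshot into `out_dir`.
#'
#' @param stations_file,detections_file Input CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param speed_mps,temperature_c Sound speed (explicit value wins).
#' @param spacing_m,min_edge_distance_m,half_extent_m Grid parameters
#'   (see [build_grid()]).
#' @param prune,station_policy Passed to [localize()].
#' @param verbose Print per-call progress and the model notice.
#' @return The results data.frame, invisibly.
#' @export
run_localize <- function(stations_file, detections_file, out_dir = ".",
                         speed_mps = NULL, temperature_c = NULL,
                         spacing_m = 0.5, min_edge_distance_m = 750,
                         half_extent_m = NULL, prune = TRUE,
                         station_policy = "earliest", verbose = TRUE) {
  .notice_once(verbose)
  stations <- read_stations(stations_file)
  detections <- read_detections(detections_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  speed <- resolve_sound_speed(speed_mps, temperature_c)
  if (length(detections) == 0L) {
    warning("no detections in ", detections_file, call. = FALSE)
    res <- results_table(list())
  } else {
    t0 <- proc.time()[["elapsed"]]
    out <- localize_batch(detections, stations, speed_mps = speed,
                          spacing_m = spacing_m,
                          min_edge_distance_m = min_edge_distance_m,
                          half_extent_m = half_extent_m, prune = prune,
                          station_policy = station_policy)
    if (verbose) {
      for (r in out) {
        if (inherits(r, "localization_result")) {
          message(sprintf("call %s: RMSE %.2f m", r$call_id, r$rmse_m))
        } else {
          message(sprintf("call %s: FAILED (%s)", r$call_id, r$message))
        }
      }
      message(sprintf("localized %d/%d calls in %.1f s",
                      sum(vapply(out, inherits, logical(1),
                                 "localization_result")),
                      length(out), proc.time()[["elapsed"]] - t0))
    }
    if (!any(vapply(out, inherits, logical(1), "localization_result"))) {
      stop(.condition("tdoa_no_feasible_cell",
                      "no call could be localized"))
    }
    res <- results_table(out)
  }
  write_results_csv(res, file.path(out_dir, "results.csv"))
  write_geojson_points(res, file.path(out_dir, "results.geojson"))
  if (nrow(res)) write_kml_points(res, file.path(out_dir, "results.kml"))
  .write_config_snapshot(out_dir, list(
    command = "localize", stations_file = stations_file,
    detections_file = detections_file, speed_mps = speed,
    spacing_m = spacing_m, min_edge_distance_m = min_edge_distance_m,
    half_extent_m = half_extent_m, prune = prune,
    station_policy = station_policy))
  invisible(res)
}

#' Simulate a scenario and write its dataset files
#'
#' Writes `stations.csv`, `detections.csv` (the dialects consumed by
#' [run_localize()]), `truth.csv` for scoring, and a config snapshot with
#' the seed.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory.
#' @return List returned by [simulate_calls()], invisibly.
#' @export
run_simulate <- function(config, out_dir = ".") {
  sim <- simulate_calls(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$stations, file.path(out_dir, "stations.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  det <- do.call(rbind, c(list(
    data.frame(call_id = character(), station_id = character(),
               time_s = numeric())),
    lapply(sim$detections, function(ds) {
      if (ds$n_stations == 0L) return(NULL)
      data.frame(call_id = ds$call_id, station_id = names(ds$times),
                 time_s = unname(ds$times))
    })))
  utils::write.csv(det, file.path(out_dir, "detections.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  snap <- unclass(config)
  snap$stations <- NULL
  snap$command <- "simulate"
  .write_config_snapshot(out_dir, snap)
  invisible(sim)
}

#' Validate retrieved positions against reference points
#'
#' Localizes each call whose `call_id` matches a reference point id and
#' reports the per-point flat-earth error plus the mean error and RMSE over
#' points - the standard whistle-validation metric.  Unmatched ids on either
#' side are listed, excluded and warned about.
#'
#' @param stations Station table, or path to a stations CSV.
#' @param detections List of [detection_set()], or path to a detections CSV.
#' @param references data.frame (`id`, `lat`, `lon`), or path to a CSV.
#' @param ... Passed to [localize()] (speed, grid, pruning, ...).
#' @return List of class `validation_report`: `per_point` data.frame
#'   (`id`, `lat`, `lon`, `ref_lat`, `ref_lon`, `error_m`, `rmse_m`),
#'   `mean_error_m`, `rmse_error_m`, `n_points`.
#' @export
run_validate <- function(stations, detections, references, ...) {
  if (is.character(stations)) stations <- read_stations(stations)
  if (is.character(detections)) detections <- read_detections(detections)
  if (is.character(references)) references <- read_references(references)
  det_ids <- vapply(detections, function(d) d$call_id, character(1))
  matched <- intersect(det_ids, references$id)
  um_det <- setdiff(det_ids, references$id)
  um_ref <- setdiff(references$id, det_ids)
  if (length(um_det) || length(um_ref)) {
    warning("unmatched point ids excluded - detections: ",
            paste(um_det, collapse = ", "), "; references: ",
            paste(um_ref, collapse = ", "), call. = FALSE)
  }
  per_point <- do.call(rbind, lapply(matched, function(id) {
    r <- localize(detections[[match(id, det_ids)]], stations, ...)
    ref <- references[references$id == id, ]
    data.frame(id = id, lat = r$lat, lon = r$lon,
               ref_lat = ref$lat, ref_lon = ref$lon,
               error_m = flat_earth_distance(r$lat, r$lon, ref$lat, ref$lon),
               rmse_m = r$rmse_m)
  }))
  if (is.null(per_point)) {
    per_point <- data.frame(id = character(), lat = numeric(),
                            lon = numeric(), ref_lat = numeric(),
                            ref_lon = numeric(), error_m = numeric(),
                            rmse_m = numeric())
  }
  structure(list(per_point = per_point,
                 mean_error_m = mean(per_point$error_m),
                 rmse_error_m = sqrt(mean(per_point$error_m^2)),
                 n_points = nrow(per_point)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d point(s): mean error %.2f m, RMSE %.2f m\n",
              x$n_points, x$mean_error_m, x$rmse_error_m))
  invisible(x)
}

#' Cluster, count and track localized calls
#'
#' Runs the full ecology layer on a localization results table: interval
#' counts over the session window, single-linkage individual clustering,
#' and a movement path per multi-call cluster.  Writes `clusters.csv`,
#' `interval_counts.csv` and `paths.geojson` when `out_dir` is given.
#'
#' @param results Results data.frame (needs `call_id`, `lat`, `lon` and
#'   `time_s`), or path to a results CSV that includes a `time_s` column.
#' @param linkage_distance_m,max_time_gap_s See [cluster_individuals()].
#' @param interval_s,session_start,session_end See [interval_counts()].
#' @param out_dir Optional output directory.
#' @return List of class `tracking_report`: `clusters`
#'   ([cluster_individuals()] result), `n_individuals`, `intervals`
#'   ([interval_counts()] result), `paths` (named list of
#'   [movement_path()] results for clusters with >= 2 calls).
#' @export
run_track <- function(results, linkage_distance_m = 50,
                      max_time_gap_s = NULL, interval_s = 600,
                      session_start = NULL, session_end = NULL,
                      out_dir = NULL) {
  if (is.character(results)) {
    results <- .read_csv_checked(results, c("call_id", "lat", "lon", "time_s"))
  }
  if (!"time_s" %in% names(results)) {
    stop(.condition("tdoa_bad_input", "results need a time_s column"))
  }
  if (is.null(session_start)) session_start <- min(results$time_s, 0)
  if (is.null(session_end)) {
    session_end <- if (nrow(results)) max(results$time_s) + 1e-9 else
      session_start + interval_s
  }
  cl <- cluster_individuals(results, linkage_distance_m, max_time_gap_s)
  iv <- interval_counts(results$time_s, interval_s, session_start,
                        session_end)
  multi <- cl$clusters$cluster_id[cl$clusters$n_calls >= 2]
  paths <- lapply(multi, function(k) {
    ids <- cl$membership$call_id[cl$membership$cluster_id == k]
    movement_path(results[results$call_id %in% ids, ])
  })
  names(paths) <- paste0("cluster", multi)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cl$membership, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(iv$counts, file.path(out_dir, "interval_counts.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    write_geojson_paths(lapply(paths, function(p) p$path),
                        file.path(out_dir, "paths.geojson"))
    .write_config_snapshot(out_dir, list(
      command = "track", linkage_distance_m = linkage_distance_m,
      max_time_gap_s = max_time_gap_s, interval_s = interval_s,
      session_start = session_start, session_end = session_end))
  }
  structure(list(clusters = cl, n_individuals = deduplicated_count(cl),
                 intervals = iv, paths = paths),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("<tracking_report> %d call(s) -> %d individual(s); mean %.2f calls/interval\n",
              nrow(x$clusters$membership), x$n_individuals, x$intervals$mean))
  invisible(x)
}
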