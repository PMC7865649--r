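# Core retrieval: detection sets -> lag distances (D_k = T_k * V) -> grid
# search minimizing the RMSE between observed and candidate lag distances.

.condition <- function(class, msg, ...) {
  structure(class = c(class, "tdoatrack_error", "error", "condition"),
            list(message = msg, call = NULL, ...))
}

#' Assemble and validate a station table
#'
#' @param stations A data.frame with columns `id`, `lat`, `lon`.  Coordinates
#'   may be decimal degrees or DMS strings (auto-detected per cell).
#' @return A data.frame with `id` (character, unique) and numeric `lat`,
#'   `lon` in decimal degrees.
#' @export
station_table <- function(stations) {
  need <- c("id", "lat", "lon")
  if (!all(need %in% names(stations))) {
    stop(.condition("tdoa_bad_input",
      paste("station table must have columns:", paste(need, collapse = ", "))))
  }
  out <- data.frame(id = as.character(stations$id),
                    lat = parse_coordinate(stations$lat),
                    lon = parse_coordinate(stations$lon),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) {
    stop(.condition("tdoa_bad_input", paste0(
      "duplicate station id: ", out$id[duplicated(out$id)][1])))
  }
  geo_point(out$lat, out$lon)  # range validation
  out
}

#' A set of detection times for one call
#'
#' Holds the times (seconds, on the shared synchronized clock) at which one
#' call was detected at each station, and derives the first detector and the
#' per-station time lags relative to it.  The absolute travel time to the
#' first detector is unknowable from the recordings and is never used.
#'
#' @param call_id Call label.
#' @param times Named numeric vector of detection times, seconds; names are
#'   station ids.  Non-finite entries are dropped.
#' @return An object of class `detection_set` with elements `call_id`,
#'   `times`, `first_station`, `lags` (seconds, all >= 0) and `n_stations`.
#' @examples
#' detection_set("E", c(Rec1 = 106.416, Rec2 = 106.316, Rec3 = 106.417))
#' @export
detection_set <- function(call_id, times) {
  if (is.null(names(times)) || any(!nzchar(names(times)))) {
    stop(.condition("tdoa_bad_input", "detection times must be named by station id"))
  }
  times <- times[is.finite(times)]
  if (anyDuplicated(names(times))) {
    stop(.condition("tdoa_bad_input", paste0(
      "duplicate detection for station ", names(times)[duplicated(names(times))][1],
      " in call ", call_id)))
  }
  first <- if (length(times)) names(times)[which.min(times)] else NA_character_
  lags <- if (length(times)) times - min(times) else numeric(0)
  structure(list(call_id = as.character(call_id), times = times,
                 first_station = first, lags = lags,
                 n_stations = length(times)),
            class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  cat("<detection_set> call", x$call_id, "-", x$n_stations, "stations;",
      "first detector:", x$first_station, "\n")
  if (x$n_stations) {
    print(round(x$lags, 4))
  }
  invisible(x)
}

#' Is a detection set localizable?
#'
#' At least three stations with finite detection times are required.
#' @param ds A [detection_set()].
#' @export
is_localizable <- function(ds) ds$n_stations >= 3L

#' Convert time lags to lag distances
#'
#' Each station's lag relative to the first detector is converted to a
#' distance `D_k = lag_k * V`.  The first detector's entry is identically 0.
#'
#' @param ds A [detection_set()] with at least three stations.
#' @param speed_mps Speed of sound in m/s.
#' @return Object of class `lag_distances`: `first_station`,
#'   `dist_by_station` (named, meters), `speed_mps`.
#' @export
lags_to_distances <- function(ds, speed_mps) {
  if (!inherits(ds, "detection_set")) ds <- do.call(detection_set, ds)
  if (ds$n_stations < 3L) {
    stop(.condition("tdoa_insufficient_detections", paste0(
      "call ", ds$call_id, ": ", ds$n_stations,
      " station(s) with finite times; localization needs at least 3")))
  }
  if (!is.finite(speed_mps) || speed_mps <= 0) {
    stop(.condition("tdoa_bad_input", "speed_mps must be positive"))
  }
  if (any(ds$lags < 0)) {
    stop(.condition("tdoa_inconsistent_clock", paste0(
      "call ", ds$call_id, ": negative lag relative to first detector ",
      ds$first_station)))
  }
  structure(list(first_station = ds$first_station,
                 dist_by_station = ds$lags * speed_mps,
                 speed_mps = speed_mps),
            class = "lag_distances")
}

#' Build the candidate search grid
#'
#' A square lattice of candidate source positions, centered on the station
#' centroid, with axes locally east (x) and north (y).  By default the
#' half-extent is the largest station-to-centroid distance plus the required
#' edge clearance, rounded up to a whole multiple of the spacing, so that
#' every recorder keeps at least `min_edge_distance_m` of clearance to each
#' grid edge.  An explicit `half_extent_m` override is accepted (e.g., to
#' reproduce a published grid size); construction fails if the override
#' leaves less clearance than required.
#'
#' @param stations Station table (see [station_table()]); at least 3 rows.
#' @param spacing_m Lattice spacing along both axes, meters (default 0.5).
#' @param min_edge_distance_m Minimum recorder-to-edge clearance, meters
#'   (default 750).  Set to 0 to allow deliberately small grids.
#' @param half_extent_m Optional explicit half-extent, meters per axis.
#' @return Object of class `grid_spec` with the center coordinates, extents
#'   and per-axis lattice size `n_axis`.
#' @export
build_grid <- function(stations, spacing_m = 0.5, min_edge_distance_m = 750,
                       half_extent_m = NULL) {
  stations <- station_table(stations)
  if (nrow(stations) < 3L) {
    stop(.condition("tdoa_bad_input", "grid construction needs >= 3 stations"))
  }
  if (!is.finite(spacing_m) || spacing_m <= 0) {
    stop(.condition("tdoa_bad_input", "spacing_m must be positive"))
  }
  center_lat <- mean(stations$lat)
  center_lon <- mean(stations$lon)
  r <- flat_earth_distance(stations$lat, stations$lon, center_lat, center_lon)
  if (max(r) < 1e-6) {
    stop(.condition("tdoa_degenerate_geometry",
                    "all stations coincide; geometry is degenerate"))
  }
  loc <- .to_local(stations$lat, stations$lon, center_lat, center_lon)
  if (.max_line_residual(loc$x, loc$y) < 1) {
    warning("stations are collinear to within 1 m; localization is ",
            "ill-conditioned perpendicular to the line", call. = FALSE)
  }
  if (is.null(half_extent_m)) {
    half_extent_m <- ceiling((max(r) + min_edge_distance_m) / spacing_m) *
      spacing_m
  } else {
    if (half_extent_m - max(r) < min_edge_distance_m) {
      stop(.condition("tdoa_grid_too_small", sprintf(
        paste0("half_extent_m = %.1f leaves %.1f m of edge clearance for the",
               " outermost station; at least %.1f m required"),
        half_extent_m, half_extent_m - max(r), min_edge_distance_m)))
    }
  }
  n_axis <- 2L * as.integer(round(half_extent_m / spacing_m)) + 1L
  structure(list(center_lat = center_lat, center_lon = center_lon,
                 half_extent_m = half_extent_m, spacing_m = spacing_m,
                 min_edge_distance_m = min_edge_distance_m,
                 n_axis = n_axis),
            class = "grid_spec")
}

# Largest perpendicular residual from the total-least-squares line through
# the points; ~0 for collinear layouts.
.max_line_residual <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sv <- svd(cbind(xc, yc))
  max(abs(cbind(xc, yc) %*% sv$v[, 2]))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %.0f m x %.0f m at %.2g m spacing (%d x %d = %s candidates)\n",
    2 * x$half_extent_m, 2 * x$half_extent_m, x$spacing_m, x$n_axis, x$n_axis,
    format(as.numeric(x$n_axis)^2, big.mark = ",")))
  cat(sprintf("  center: %.6f, %.6f; min edge clearance %.0f m\n",
              x$center_lat, x$center_lon, x$min_edge_distance_m))
  invisible(x)
}

# Lattice coordinates in row-major scan order: south-to-north rows,
# west-to-east within each row (the deterministic tie-break order).
.grid_latlon <- function(grid) {
  off <- seq(-grid$half_extent_m, grid$half_extent_m, by = grid$spacing_m)
  ll <- .from_local(off, off, grid$center_lat, grid$center_lon)
  list(lat = rep(ll$lat, each = grid$n_axis),
       lon = rep(ll$lon, times = grid$n_axis))
}

#' Evaluate candidate source positions against observed lag distances
#'
#' For each candidate point, computes the flat-earth distance to every
#' station, identifies the nearest station, and (when the nearest station is
#' the observed first detector) forms the candidate lag distances
#' `D*_k = Dinv*_k - Dmin*` for the remaining stations and the RMSE against
#' the observed lag distances.  Candidates whose nearest station differs
#' from the first detector are skipped (returned as `NA`), which is how the
#' search is pruned to the first detector's region; set `prune = FALSE` to
#' score every candidate regardless.
#'
#' A candidate equidistant (within `tie_tol_m`) to the first detector and
#' another station counts as matching, so near-zero-lag sources on region
#' boundaries are not spuriously discarded.
#'
#' @param lat,lon Candidate coordinates, decimal degrees (vectorized).
#' @param stations Station table restricted to the stations in `lagdist`.
#' @param lagdist A [lags_to_distances()] result.
#' @param tie_tol_m Nearest-station tie tolerance in meters (default 0).
#' @param prune Apply the nearest-recorder skip rule (default `TRUE`).
#' @return Numeric vector of RMSE values in meters; `NA` marks skipped
#'   candidates.
#' @export
evaluate_candidate <- function(lat, lon, stations, lagdist, tie_tol_m = 0,
                               prune = TRUE) {
  stations <- station_table(stations)
  ids <- stations$id
  obs <- lagdist$dist_by_station
  if (!all(names(obs) %in% ids) || !all(ids %in% names(obs))) {
    stop(.condition("tdoa_bad_input",
                    "stations and lag distances name different station sets"))
  }
  j <- match(lagdist$first_station, ids)
  d <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d[[k]] <- flat_earth_distance(lat, lon, stations$lat[k], stations$lon[k])
  }
  dmin <- d[[1]]
  for (k in seq_along(ids)[-1]) dmin <- pmin(dmin, d[[k]])
  others <- seq_along(ids)[-j]
  ss <- 0
  for (k in others) {
    resid <- (d[[k]] - dmin) - obs[[ids[k]]]
    ss <- ss + resid * resid
  }
  rmse <- sqrt(ss / length(others))
  if (prune) rmse[d[[j]] > dmin + tie_tol_m] <- NA_real_
  rmse
}

#' Localize one call by exhaustive grid search
#'
#' Converts the call's time lags to lag distances at the working sound speed
#' and scans every lattice point of the grid, keeping the candidate with the
#' minimum lag-distance RMSE (ties broken by scan order: south-to-north,
#' west-to-east).  With more than three detecting stations a three-station
#' subset is chosen first (see `station_policy`); the method itself is
#' defined for three recorders.
#'
#' @param ds A [detection_set()].
#' @param stations Station table covering (at least) the detecting stations.
#' @param speed_mps Explicit sound speed (m/s); overrides `temperature_c`.
#' @param temperature_c Air temperature used to model the speed when
#'   `speed_mps` is not given.
#' @param grid A [build_grid()] result; built from the stations used when
#'   omitted.
#' @param spacing_m,min_edge_distance_m,half_extent_m Grid parameters used
#'   only when `grid` is omitted.
#' @param prune Restrict the search to candidates whose nearest recorder is
#'   the first detector (default `TRUE`).
#' @param tie_tol_m Nearest-recorder tie tolerance; defaults to one lattice
#'   spacing.
#' @param station_policy With > 3 detecting stations: `"earliest"` keeps the
#'   three earliest detectors, `"best_triple"` evaluates every 3-subset and
#'   keeps the lowest-RMSE result.  Both are heuristics, not part of the
#'   three-recorder method proper.
#' @return Object of class `localization_result`: `call_id`, `lat`, `lon`,
#'   `rmse_m`, `first_station`, `n_candidates_evaluated`,
#'   `n_stations_used`, `stations_used`, `grid`.
#' @export
localize <- function(ds, stations, speed_mps = NULL, temperature_c = NULL,
                     grid = NULL, spacing_m = 0.5, min_edge_distance_m = 750,
                     half_extent_m = NULL, prune = TRUE, tie_tol_m = NULL,
                     station_policy = c("earliest", "best_triple")) {
  station_policy <- match.arg(station_policy)
  stations <- station_table(stations)
  speed <- resolve_sound_speed(speed_mps, temperature_c)
  have <- intersect(stations$id, names(ds$times))
  if (length(have) < 3L) {
    stop(.condition("tdoa_insufficient_detections", paste0(
      "call ", ds$call_id, ": only ", length(have),
      " detecting station(s) present in the station table")))
  }
  if (length(have) > 3L) {
    if (station_policy == "earliest") {
      keep <- names(sort(ds$times[have]))[1:3]
      return(localize(detection_set(ds$call_id, ds$times[keep]),
                      stations[stations$id %in% keep, ], speed_mps = speed,
                      grid = grid, spacing_m = spacing_m,
                      min_edge_distance_m = min_edge_distance_m,
                      half_extent_m = half_extent_m, prune = prune,
                      tie_tol_m = tie_tol_m))
    }
    triples <- utils::combn(have, 3, simplify = FALSE)
    best <- NULL
    for (tr in triples) {
      res <- tryCatch(
        localize(detection_set(ds$call_id, ds$times[tr]),
                 stations[stations$id %in% tr, ], speed_mps = speed,
                 grid = grid, spacing_m = spacing_m,
                 min_edge_distance_m = min_edge_distance_m,
                 half_extent_m = half_extent_m, prune = prune,
                 tie_tol_m = tie_tol_m),
        tdoa_no_feasible_cell = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$rmse_m < best$rmse_m)) {
        best <- res
      }
    }
    if (is.null(best)) {
      stop(.condition("tdoa_no_feasible_cell", paste0(
        "call ", ds$call_id, ": no feasible candidate for any 3-subset")))
    }
    return(best)
  }
  st_used <- stations[stations$id %in% have, , drop = FALSE]
  ds_used <- detection_set(ds$call_id, ds$times[st_used$id])
  lagdist <- lags_to_distances(ds_used, speed)
  if (is.null(grid)) {
    grid <- build_grid(st_used, spacing_m = spacing_m,
                       min_edge_distance_m = min_edge_distance_m,
                       half_extent_m = half_extent_m)
  }
  if (is.null(tie_tol_m)) tie_tol_m <- grid$spacing_m
  g <- .grid_latlon(grid)
  rmse <- evaluate_candidate(g$lat, g$lon, st_used, lagdist,
                             tie_tol_m = tie_tol_m, prune = prune)
  n_eval <- sum(!is.na(rmse))
  if (n_eval == 0L) {
    stop(.condition("tdoa_no_feasible_cell", paste0(
      "call ", ds_used$call_id, ": every grid candidate was skipped ",
      "(first detector ", lagdist$first_station,
      " is nearest to no lattice point)")))
  }
  i <- which.min(rmse)
  structure(list(call_id = ds_used$call_id,
                 lat = g$lat[i], lon = g$lon[i],
                 rmse_m = rmse[i],
                 first_station = lagdist$first_station,
                 n_candidates_evaluated = n_eval,
                 n_stations_used = nrow(st_used),
                 stations_used = st_used$id,
                 speed_mps = speed,
                 grid = grid),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf(
    "<localization_result> call %s: %.6f, %.6f (RMSE %.2f m)\n",
    x$call_id, x$lat, x$lon, x$rmse_m))
  cat(sprintf("  first detector %s; %d stations; %s candidates evaluated\n",
              x$first_station, x$n_stations_used,
              format(x$n_candidates_evaluated, big.mark = ",")))
  invisible(x)
}

#' Localize a batch of calls over a shared deployment
#'
#' Order-preserving; a call that cannot be localized yields a
#' `localization_failure` entry instead of aborting the batch.
#'
#' @param detections List of [detection_set()] objects.
#' @param stations Station table shared by all calls.
#' @param grid Shared [build_grid()] result; built once from the full
#'   station table (using `spacing_m`, `min_edge_distance_m`,
#'   `half_extent_m`) when omitted.
#' @param spacing_m,min_edge_distance_m,half_extent_m Grid parameters used
#'   only when `grid` is omitted.
#' @param ... Passed to [localize()] (speed, pruning, station policy, ...).
#' @return List (same length and order as `detections`) of
#'   `localization_result` or `localization_failure` objects.
#' @seealso [results_table()]
#' @export
localize_batch <- function(detections, stations, grid = NULL,
                           spacing_m = 0.5, min_edge_distance_m = 750,
                           half_extent_m = NULL, ...) {
  stations <- station_table(stations)
  if (length(detections) == 0L) return(list())
  if (is.null(grid)) {
    grid <- build_grid(stations, spacing_m = spacing_m,
                       min_edge_distance_m = min_edge_distance_m,
                       half_extent_m = half_extent_m)
  }
  lapply(detections, function(ds) {
    tryCatch(localize(ds, stations, grid = grid, ...),
             tdoatrack_error = function(e) {
               structure(list(call_id = ds$call_id,
                              message = conditionMessage(e),
                              class_chain = class(e)[1]),
                         class = "localization_failure")
             })
  })
}

#' Tabulate batch localization results
#'
#' @param results Output of [localize_batch()].
#' @param warn Emit a warning listing failed calls (default `TRUE`).
#' @return data.frame with columns `call_id`, `lat`, `lon`, `rmse_m`,
#'   `first_station`, `n_stations_used` (one row per successful call).
#' @export
results_table <- function(results, warn = TRUE) {
  ok <- vapply(results, inherits, logical(1), "localization_result")
  if (warn && any(!ok)) {
    warning(sum(!ok), " call(s) failed to localize: ",
            paste(vapply(results[!ok], function(f) f$call_id, character(1)),
                  collapse = ", "), call. = FALSE)
  }
  if (!any(ok)) {
    return(data.frame(call_id = character(), lat = numeric(), lon = numeric(),
                      rmse_m = numeric(), first_station = character(),
                      n_stations_used = integer()))
  }
  do.call(rbind, lapply(results[ok], function(r) {
    data.frame(call_id = r$call_id, lat = r$lat, lon = r$lon,
               rmse_m = r$rmse_m, first_station = r$first_station,
               n_stations_used = r$n_stations_used)
  }))
}
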