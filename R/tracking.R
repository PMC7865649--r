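# Ecology layer: per-interval call accumulation, collapsing of repetitive
# calls from the same territorial individual by spatial single-linkage
# clustering, and movement-path summaries per individual.

#' Per-interval call counts and summary statistics
#'
#' Partitions in-session calls (`session_start <= t < session_end`) into
#' consecutive intervals of `interval_s` seconds and reports the count per
#' interval plus the mean and standard deviation across intervals.
#'
#' @param time_s Numeric vector of call times, seconds (or any consistent
#'   clock).
#' @param interval_s Interval length, seconds (e.g., 600 for 10 min).
#' @param session_start,session_end Session window; `session_end` must
#'   exceed `session_start`.  A final partial interval is kept and flagged.
#' @param sd_type `"population"` (divide by the number of intervals) or
#'   `"sample"` (divide by n-1).
#' @return Object of class `interval_counts`: `counts` data.frame
#'   (`interval`, `start_s`, `end_s`, `count`, `truncated`), `n_calls`,
#'   `mean`, `sd`, `sd_type`.  An empty window yields zero intervals.
#' @export
interval_counts <- function(time_s, interval_s, session_start, session_end,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.finite(interval_s) || interval_s <= 0) {
    stop(.condition("tdoa_bad_input", "interval_s must be positive"))
  }
  if (session_end <= session_start) {
    stop(.condition("tdoa_bad_input",
                    "session_end must be after session_start"))
  }
  len <- session_end - session_start
  n_int <- ceiling(len / interval_s)
  if (n_int == 0L) {
    counts <- data.frame(interval = integer(), start_s = numeric(),
                         end_s = numeric(), count = integer(),
                         truncated = logical())
    return(structure(list(counts = counts, n_calls = 0L, mean = NaN,
                          sd = NaN, sd_type = sd_type),
                     class = "interval_counts"))
  }
  starts <- session_start + (seq_len(n_int) - 1) * interval_s
  ends <- pmin(starts + interval_s, session_end)
  truncated <- ends - starts < interval_s
  if (any(truncated)) {
    warning("final interval truncated to ", ends[n_int] - starts[n_int],
            " s", call. = FALSE)
  }
  inside <- time_s[time_s >= session_start & time_s < session_end]
  idx <- pmin(floor((inside - session_start) / interval_s) + 1, n_int)
  count <- tabulate(idx, nbins = n_int)
  m <- mean(count)
  s <- if (sd_type == "population") sqrt(mean((count - m)^2)) else
    stats::sd(count)
  structure(list(counts = data.frame(interval = seq_len(n_int),
                                     start_s = starts, end_s = ends,
                                     count = count, truncated = truncated),
                 n_calls = length(inside), mean = m, sd = s,
                 sd_type = sd_type),
            class = "interval_counts")
}

#' @export
print.interval_counts <- function(x, ...) {
  cat(sprintf("<interval_counts> %d calls in %d intervals: mean %.2f, %s sd %.2f\n",
              x$n_calls, nrow(x$counts), x$mean, x$sd_type, x$sd))
  invisible(x)
}

#' Group localized calls into putative individuals
#'
#' Territorial males keep exclusive areas, so calls localized to adjacent
#' positions are attributed to one individual.  Clusters are the connected
#' components of the graph linking every pair of calls whose flat-earth
#' distance is at most `linkage_distance_m` (single-linkage agglomeration);
#' the definition is independent of input order.  An optional time gate
#' additionally requires linked calls to be within `max_time_gap_s`; it is
#' off by default because territorial individuals re-call on scales of tens
#' of minutes.
#'
#' @param calls data.frame with `call_id`, `lat`, `lon` and (optionally)
#'   `time_s`.
#' @param linkage_distance_m Linkage threshold, meters (default 50,
#'   matching the proximity at which calls and a camera-trapped male were
#'   judged to be the same animal).
#' @param max_time_gap_s Optional maximum time difference for a link.
#' @return List of class `individual_clusters`: `membership` data.frame
#'   (`cluster_id`, `call_id`), `clusters` data.frame (`cluster_id`,
#'   `n_calls`, `centroid_lat`, `centroid_lon`, `first_time`, `last_time`),
#'   and the parameters used.
#' @export
cluster_individuals <- function(calls, linkage_distance_m = 50,
                                max_time_gap_s = NULL) {
  if (!is.finite(linkage_distance_m) || linkage_distance_m <= 0) {
    stop(.condition("tdoa_bad_input", "linkage_distance_m must be positive"))
  }
  need <- c("call_id", "lat", "lon")
  if (!all(need %in% names(calls))) {
    stop(.condition("tdoa_bad_input",
                    "calls need columns call_id, lat, lon"))
  }
  n <- nrow(calls)
  has_time <- "time_s" %in% names(calls)
  if (n == 0L) {
    return(structure(list(
      membership = data.frame(cluster_id = integer(), call_id = character()),
      clusters = data.frame(cluster_id = integer(), n_calls = integer(),
                            centroid_lat = numeric(), centroid_lon = numeric(),
                            first_time = numeric(), last_time = numeric()),
      linkage_distance_m = linkage_distance_m,
      max_time_gap_s = max_time_gap_s), class = "individual_clusters"))
  }
  pair <- which(upper.tri(matrix(NA, n, n)), arr.ind = TRUE)
  d <- flat_earth_distance(calls$lat[pair[, 1]], calls$lon[pair[, 1]],
                           calls$lat[pair[, 2]], calls$lon[pair[, 2]])
  link <- d <= linkage_distance_m
  if (!is.null(max_time_gap_s)) {
    if (!has_time) {
      stop(.condition("tdoa_bad_input",
                      "time gating needs a time_s column"))
    }
    link <- link &
      abs(calls$time_s[pair[, 1]] - calls$time_s[pair[, 2]]) <= max_time_gap_s
  }
  g <- igraph::graph_from_edgelist(
    cbind(pair[link, 1], pair[link, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  # stable ids: clusters numbered by first appearance in the input
  comp <- match(comp, unique(comp))
  membership <- data.frame(cluster_id = comp, call_id = calls$call_id,
                           stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(sort(unique(comp)), function(k) {
    sel <- comp == k
    data.frame(cluster_id = k, n_calls = sum(sel),
               centroid_lat = mean(calls$lat[sel]),
               centroid_lon = mean(calls$lon[sel]),
               first_time = if (has_time) min(calls$time_s[sel]) else NA_real_,
               last_time = if (has_time) max(calls$time_s[sel]) else NA_real_)
  }))
  structure(list(membership = membership, clusters = summ,
                 linkage_distance_m = linkage_distance_m,
                 max_time_gap_s = max_time_gap_s),
            class = "individual_clusters")
}

#' @export
print.individual_clusters <- function(x, ...) {
  cat(sprintf("<individual_clusters> %d call(s) -> %d individual(s) at %.0f m linkage\n",
              nrow(x$membership), nrow(x$clusters), x$linkage_distance_m))
  invisible(x)
}

#' Number of unique individuals after collapsing repetitive calls
#'
#' @param clusters A [cluster_individuals()] result.
#' @return Integer count of clusters; non-increasing in the linkage
#'   threshold that produced them.
#' @export
deduplicated_count <- function(clusters) {
  stopifnot(inherits(clusters, "individual_clusters"))
  nrow(clusters$clusters)
}

#' Movement path of one individual's calls
#'
#' Orders a cluster's calls by time and summarizes the track: the polyline,
#' the total path length, the net displacement from first to last call, and
#' the net bearing (degrees clockwise from north).
#'
#' @param calls data.frame with `call_id`, `lat`, `lon`, `time_s` for the
#'   calls of one cluster.
#' @return List of class `movement_path`: `path` (time-ordered data.frame),
#'   `net_displacement_m`, `path_length_m`, `bearing_deg` (NA for fewer
#'   than 2 calls).
#' @export
movement_path <- function(calls) {
  need <- c("call_id", "lat", "lon", "time_s")
  if (!all(need %in% names(calls))) {
    stop(.condition("tdoa_bad_input",
                    "calls need columns call_id, lat, lon, time_s"))
  }
  path <- calls[order(calls$time_s), need, drop = FALSE]
  n <- nrow(path)
  if (n < 2L) {
    return(structure(list(path = path[0, ], net_displacement_m = 0,
                          path_length_m = 0, bearing_deg = NA_real_),
                     class = "movement_path"))
  }
  seg <- flat_earth_distance(path$lat[-n], path$lon[-n],
                             path$lat[-1], path$lon[-1])
  structure(list(
    path = path,
    net_displacement_m = flat_earth_distance(path$lat[1], path$lon[1],
                                             path$lat[n], path$lon[n]),
    path_length_m = sum(seg),
    bearing_deg = bearing_deg(path$lat[1], path$lon[1],
                              path$lat[n], path$lon[n])),
    class = "movement_path")
}

#' @export
print.movement_path <- function(x, ...) {
  cat(sprintf("<movement_path> %d fixes: net %.1f m at %.0f deg (path %.1f m)\n",
              nrow(x$path), x$net_displacement_m, x$bearing_deg,
              x$path_length_m))
  invisible(x)
}
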