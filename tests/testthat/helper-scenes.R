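# Shared scene builders: small recorder arrays laid out in a local
# east/north frame and noise-free forward-modeled detection sets.

R_EARTH <- 6371000
DEG <- pi / 180

# Station table from local east/north offsets (meters) about a center.
local_stations <- function(x, y, center_lat = 35.66, center_lon = 139.68,
                           ids = sprintf("Rec%d", seq_along(x))) {
  lat <- center_lat + (y / R_EARTH) / DEG
  lon <- center_lon + (x / (R_EARTH * cos(center_lat * DEG))) / DEG
  data.frame(id = ids, lat = lat, lon = lon, stringsAsFactors = FALSE)
}

local_point <- function(x, y, center_lat = 35.66, center_lon = 139.68) {
  data.frame(lat = center_lat + (y / R_EARTH) / DEG,
             lon = center_lon + (x / (R_EARTH * cos(center_lat * DEG))) / DEG)
}

# Noise-free forward model: detection time at each station is the
# propagation delay (flat-earth distance / speed) plus optional Gaussian
# timing noise.
forward_detections <- function(call_id, src_lat, src_lon, stations,
                               speed_mps = 340, noise_sd = 0, t0 = 0) {
  d <- flat_earth_distance(src_lat, src_lon, stations$lat, stations$lon)
  times <- t0 + d / speed_mps
  if (noise_sd > 0) times <- times + stats::rnorm(length(d), 0, noise_sd)
  names(times) <- stations$id
  detection_set(call_id, times)
}

# Uniform sample inside the triangle of the first three stations
# (barycentric coordinates).
sample_in_triangle <- function(n, stations) {
  a <- stats::runif(n); b <- stats::runif(n)
  flip <- a + b > 1
  a[flip] <- 1 - a[flip]; b[flip] <- 1 - b[flip]
  lat <- stations$lat[1] + a * (stations$lat[2] - stations$lat[1]) +
    b * (stations$lat[3] - stations$lat[1])
  lon <- stations$lon[1] + a * (stations$lon[2] - stations$lon[1]) +
    b * (stations$lon[3] - stations$lon[1])
  data.frame(lat = lat, lon = lon)
}

# First-order retrieval-error bound for a noise-free source: the argmin of
# the lag-distance RMSE over the lattice lies within
# cond(J) * half-lattice-diagonal of the source, where J has rows
# unit(src -> station_k) - unit(src -> first detector) for the two
# non-first stations (the Jacobian of the lag distances in the local
# plane).  Derived independently of the search implementation.
lattice_error_bound <- function(src_lat, src_lon, stations, first_id,
                                spacing_m) {
  unit_to <- function(lat, lon) {
    dx <- (lon - src_lon) * DEG * cos(src_lat * DEG) * R_EARTH
    dy <- (lat - src_lat) * DEG * R_EARTH
    c(dx, dy) / sqrt(dx^2 + dy^2)
  }
  j <- match(first_id, stations$id)
  uf <- unit_to(stations$lat[j], stations$lon[j])
  J <- t(vapply(setdiff(seq_len(nrow(stations)), j), function(k) {
    unit_to(stations$lat[k], stations$lon[k]) - uf
  }, numeric(2)))
  sv <- svd(J)$d
  (sv[1] / sv[2]) * 0.5 * spacing_m * sqrt(2)
}

# Uniform in-triangle sources at least `min_station_dist` from every
# recorder (very close sources make the two hyperbolic constraints nearly
# degenerate and can admit a distant ghost intersection).
sample_in_triangle_clear <- function(n, stations, min_station_dist = 20) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    p <- sample_in_triangle(n, stations)
    d <- vapply(seq_len(nrow(stations)), function(k) {
      flat_earth_distance(p$lat, p$lon, stations$lat[k], stations$lon[k])
    }, numeric(n))
    keep <- apply(matrix(d, nrow = n), 1, min) >= min_station_dist
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Convenience: localize over a deliberately small grid around the array
# (for test-scale runtimes the published defaults are overridden here).
localize_small <- function(ds, stations, half_extent_m, spacing_m = 0.5,
                           speed_mps = 340, ...) {
  grid <- build_grid(stations, spacing_m = spacing_m,
                     min_edge_distance_m = 0, half_extent_m = half_extent_m)
  localize(ds, stations, speed_mps = speed_mps, grid = grid, ...)
}
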