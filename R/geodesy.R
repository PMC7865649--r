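# Geographic primitives: DMS parsing, the flat-earth (equirectangular)
# distance used throughout the localization, and the dry-air sound-speed
# model.  Public API works in decimal degrees; radians are internal only.

#' Mean Earth radius in meters
#'
#' The spherical Earth radius used by [flat_earth_distance()] and all grid
#' constructions (6,371,000 m).
#' @export
EARTH_RADIUS_M <- 6371000

.deg2rad <- pi / 180

#' Construct validated geographic points
#'
#' @param lat Latitude in decimal degrees north (negative = south).
#' @param lon Longitude in decimal degrees east (negative = west).
#' @return A `data.frame` with columns `lat` and `lon` (class `geo_point`).
#' @examples
#' geo_point(35.6605889, 139.6817028)
#' @export
geo_point <- function(lat, lon) {
  lat <- as.numeric(lat)
  lon <- as.numeric(lon)
  if (length(lat) != length(lon)) {
    stop("`lat` and `lon` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude outside [-90, 90]: ", lat[which(lat < -90 | lat > 90)[1]],
         call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude outside [-180, 180]: ",
         lon[which(lon < -180 | lon > 180)[1]], call. = FALSE)
  }
  structure(data.frame(lat = lat, lon = lon),
            class = c("geo_point", "data.frame"))
}

# Matches D deg M' S.ss" H with ASCII or typographic symbol variants
# (degree sign/masculine ordinal; prime/apostrophes; double prime/quotes).
.dms_regex <- paste0(
  "^([0-9]{1,3})\\s*[\u00b0\u00ba]\\s*",                # degrees
  "([0-9]{1,2})\\s*[\u2032'\u2019]\\s*",                # minutes
  "([0-9]{1,2}(?:\\.[0-9]+)?)\\s*[\u2033\"\u201d]\\s*", # seconds
  "([NSEW])$"
)

#' Parse a degrees-minutes-seconds coordinate string
#'
#' Accepts strings of the form `35 deg 39' 38.12" N` with either ASCII
#' (`'`, `"`) or typographic (`\u2032`, `\u2033`) minute/second marks and
#' optional whitespace between tokens.  Southern and western hemisphere
#' letters negate the value.
#'
#' @param x Character vector of DMS strings.
#' @return Numeric vector of decimal degrees.
#' @examples
#' parse_dms("35\u00b039\u203238.12\u2033 N")
#' @seealso [format_dms()], [parse_coordinate()]
#' @export
parse_dms <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec(.dms_regex, x))
  vapply(seq_along(x), function(i) {
    g <- m[[i]]
    if (length(g) == 0L) {
      stop("not a valid DMS coordinate: '", x[i], "'", call. = FALSE)
    }
    d <- as.numeric(g[2]); mi <- as.numeric(g[3]); s <- as.numeric(g[4])
    hemi <- g[5]
    if (mi >= 60) {
      stop("minutes must be < 60 in '", x[i], "' (got ", g[3], ")",
           call. = FALSE)
    }
    if (s >= 60) {
      stop("seconds must be < 60 in '", x[i], "' (got ", g[4], ")",
           call. = FALSE)
    }
    maxd <- if (hemi %in% c("N", "S")) 90 else 180
    deg <- d + mi / 60 + s / 3600
    if (deg > maxd) {
      stop("coordinate out of range in '", x[i], "'", call. = FALSE)
    }
    if (hemi %in% c("S", "W")) -deg else deg
  }, numeric(1))
}

#' Format decimal degrees as a DMS string
#'
#' Inverse of [parse_dms()]: `parse_dms(format_dms(x, axis))` reproduces `x`
#' to better than 0.01 arc-seconds.
#'
#' @param deg Numeric vector of decimal degrees.
#' @param axis `"lat"` or `"lon"`; selects the hemisphere letters (N/S, E/W).
#' @param digits Decimal places for the seconds field.
#' @return Character vector.
#' @export
format_dms <- function(deg, axis = c("lat", "lon"), digits = 2) {
  axis <- match.arg(axis)
  hemi <- if (axis == "lat") ifelse(deg < 0, "S", "N") else
    ifelse(deg < 0, "W", "E")
  a <- abs(deg)
  d <- floor(a)
  mi <- floor((a - d) * 60)
  s <- round(((a - d) * 60 - mi) * 60, digits)
  # carry after rounding seconds up to 60
  carry <- s >= 60
  s[carry] <- 0
  mi[carry] <- mi[carry] + 1
  d[mi >= 60] <- d[mi >= 60] + 1
  mi[mi >= 60] <- 0
  sprintf("%d\u00b0%d\u2032%.*f\u2033 %s", d, mi, digits, s, hemi)
}

#' Parse a coordinate cell that may be DMS or decimal degrees
#'
#' Auto-detects per element: values containing a hemisphere letter are parsed
#' as DMS, everything else as plain decimal degrees.
#'
#' @param x Character or numeric vector.
#' @return Numeric decimal degrees.
#' @export
parse_coordinate <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  is_dms <- grepl("[NSEW]", x)
  if (any(is_dms)) out[is_dms] <- parse_dms(x[is_dms])
  if (any(!is_dms)) {
    v <- suppressWarnings(as.numeric(x[!is_dms]))
    if (any(is.na(v))) {
      stop("cannot parse coordinate '", x[!is_dms][which(is.na(v))[1]], "'",
           call. = FALSE)
    }
    out[!is_dms] <- v
  }
  out
}

#' Flat-earth (equirectangular) distance between points
#'
#' Planar distance on a sphere of radius `radius_m` using the standard
#' small-area equirectangular approximation:
#' \deqn{d = R \sqrt{x^2 + y^2},\quad
#'       x = \Delta\lambda \cos\bar\varphi,\quad y = \Delta\varphi}
#' with \eqn{\bar\varphi} the mean latitude of the pair (all angles in
#' radians).  The east-west term scales the longitude difference by the
#' cosine of the mean latitude and the north-south term is the latitude
#' difference.  Intended for separations of at most a few kilometers, where
#' it agrees with great-circle distance to well under 0.1%.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized,
#'   recycled).
#' @param radius_m Sphere radius in meters; defaults to [EARTH_RADIUS_M].
#' @return Distances in meters.
#' @export
flat_earth_distance <- function(lat1, lon1, lat2, lon2,
                                radius_m = EARTH_RADIUS_M) {
  stopifnot(radius_m > 0)
  x <- (lon2 - lon1) * .deg2rad * cos((lat1 + lat2) / 2 * .deg2rad)
  y <- (lat2 - lat1) * .deg2rad
  radius_m * sqrt(x * x + y * y)
}

#' Speed of sound in dry air
#'
#' Linear approximation `v = 331.2 + 0.606 * T` (m/s, `T` in degrees
#' Celsius), anchored at 331.2 m/s for 0 degrees C and 343.3 m/s (343 after
#' integer rounding) at 20 degrees C.
#'
#' @param temp_c Air temperature in degrees Celsius, within [-40, 50].
#' @return Speed in meters per second.
#' @examples
#' speed_of_sound(0)   # 331.2
#' speed_of_sound(20)  # 343.32
#' @export
speed_of_sound <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c < -40 | temp_c > 50)) {
    stop("temperature must be finite and within [-40, 50] degrees C",
         call. = FALSE)
  }
  331.2 + 0.606 * temp_c
}

#' Resolve the sound speed from an explicit value or a temperature
#'
#' An explicit `speed_mps` always takes precedence over the temperature
#' model (field campaigns often fix a round value such as 340 m/s).
#'
#' @param speed_mps Explicit speed in m/s, or `NULL`.
#' @param temperature_c Air temperature in degrees C, or `NULL`.
#' @return Speed in meters per second.
#' @export
resolve_sound_speed <- function(speed_mps = NULL, temperature_c = NULL) {
  if (!is.null(speed_mps)) {
    if (!is.finite(speed_mps) || speed_mps <= 0) {
      stop("speed_mps must be a positive number", call. = FALSE)
    }
    return(as.numeric(speed_mps))
  }
  if (!is.null(temperature_c)) return(speed_of_sound(temperature_c))
  stop("provide either speed_mps or temperature_c", call. = FALSE)
}

# Local east/north (meters) offsets of points relative to an origin; the
# inverse of the lattice construction in build_grid().  Longitude scaling
# uses the origin latitude so that to_local/from_local round-trip exactly.
.to_local <- function(lat, lon, origin_lat, origin_lon,
                      radius_m = EARTH_RADIUS_M) {
  list(x = (lon - origin_lon) * .deg2rad * cos(origin_lat * .deg2rad) *
         radius_m,
       y = (lat - origin_lat) * .deg2rad * radius_m)
}

.from_local <- function(x, y, origin_lat, origin_lon,
                        radius_m = EARTH_RADIUS_M) {
  list(lat = origin_lat + (y / radius_m) / .deg2rad,
       lon = origin_lon + (x / (radius_m * cos(origin_lat * .deg2rad))) /
         .deg2rad)
}

#' Bearing from one point to another
#'
#' Compass bearing (degrees clockwise from north) of the second point as
#' seen from the first, under the local flat-earth frame.
#'
#' @inheritParams flat_earth_distance
#' @return Bearing in degrees within [0, 360).
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  loc <- .to_local(lat2, lon2, lat1, lon1)
  (atan2(loc$x, loc$y) / .deg2rad) %% 360
}
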