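# File formats.  All CSV dialects are UTF-8, comma-separated with a header
# row.  GeoJSON is written via jsonlite; KML as a minimal Placemark
# document (points and line strings only - the map-overlay handoff).

#' Read a station table from CSV
#'
#' Expected columns: `id`, `lat`, `lon`; coordinates may be decimal degrees
#' or DMS strings, auto-detected per cell.
#' @param path CSV file path.
#' @return Validated station data.frame.
#' @export
read_stations <- function(path) {
  df <- .read_csv_checked(path, c("id", "lat", "lon"))
  station_table(df)
}

#' Read long-format call detections from CSV
#'
#' Expected columns: `call_id`, `station_id`, `time_s` (seconds on the
#' shared synchronized clock).  Rows are grouped by `call_id` in order of
#' first appearance.
#' @param path CSV file path.
#' @return List of [detection_set()] objects.
#' @export
read_detections <- function(path) {
  df <- .read_csv_checked(path, c("call_id", "station_id", "time_s"))
  if (nrow(df) == 0L) return(list())
  t <- suppressWarnings(as.numeric(df$time_s))
  if (any(is.na(t) & !is.na(df$time_s))) {
    bad <- which(is.na(t) & !is.na(df$time_s))[1]
    stop(.condition("tdoa_bad_input", paste0(
      "non-numeric time_s at data line ", bad, " of ", path,
      ": '", df$time_s[bad], "'")))
  }
  ids <- unique(as.character(df$call_id))
  lapply(ids, function(cid) {
    sel <- df$call_id == cid
    times <- t[sel]
    names(times) <- as.character(df$station_id[sel])
    detection_set(cid, times)
  })
}

#' Read reference validation points from CSV
#'
#' Expected columns: `id`, `lat`, `lon` (DMS or decimal degrees).
#' @param path CSV file path.
#' @return data.frame with `id`, numeric `lat`, `lon`.
#' @export
read_references <- function(path) {
  df <- .read_csv_checked(path, c("id", "lat", "lon"))
  data.frame(id = as.character(df$id),
             lat = parse_coordinate(df$lat),
             lon = parse_coordinate(df$lon),
             stringsAsFactors = FALSE)
}

.read_csv_checked <- function(path, need) {
  if (!file.exists(path)) {
    stop(.condition("tdoa_bad_input", paste0("file not found: ", path)))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) {
      stop(.condition("tdoa_bad_input", paste0(
        "cannot parse CSV ", path, ": ", conditionMessage(e))))
    })
  if (!all(need %in% names(df))) {
    stop(.condition("tdoa_bad_input", paste0(
      path, " must have columns: ", paste(need, collapse = ", "),
      " (found: ", paste(names(df), collapse = ", "), ")")))
  }
  df
}

#' Write localization results to CSV
#'
#' @param results data.frame from [results_table()] (or compatible).
#' @param path Output CSV path.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write point features as a GeoJSON FeatureCollection
#'
#' @param df data.frame with `lat`, `lon` and any property columns.
#' @param path Output path.
#' @export
write_geojson_points <- function(df, path) {
  props <- setdiff(names(df), c("lat", "lon"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write movement paths as GeoJSON LineStrings
#'
#' @param paths Named list of data.frames with `lat`, `lon` in path order.
#' @param path Output path.
#' @export
write_geojson_paths <- function(paths, path) {
  features <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(p)), function(i) {
                           c(p$lon[i], p$lat[i])
                         })),
         properties = list(id = nm, n_points = nrow(p)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write point features as a minimal KML document
#'
#' @param df data.frame with `lat`, `lon` and a `name` (or `call_id`)
#'   column.
#' @param path Output path.
#' @export
write_kml_points <- function(df, path) {
  nm <- if ("name" %in% names(df)) df$name else
    if ("call_id" %in% names(df)) df$call_id else seq_len(nrow(df))
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  pm <- sprintf(
    "    <Placemark><name>%s</name><Point><coordinates>%.10f,%.10f,0</coordinates></Point></Placemark>",
    esc(nm), df$lon, df$lat)
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<kml xmlns="http://www.opengis.net/kml/2.2">',
               "  <Document>", pm, "  </Document>", "</kml>"),
             path, useBytes = TRUE)
  invisible(path)
}
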