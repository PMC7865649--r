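# Built-in deployment fixtures: the two field campaigns this method was
# developed on - a university playground array (three recorders, five
# whistle reference points) and an Oze marshland array (four recorders,
# five reference points).  Coordinates are kept in their original DMS form
# and parsed on access, exercising the same path as user CSV input.

.dms <- function(d, m, s, hemi) {
  sprintf("%d\u00b0%d\u2032%.2f\u2033 %s", d, m, s, hemi)
}

#' Playground (UTokyo) validation deployment
#'
#' Three recorders around a 90 m x 55 m playground plus five reference
#' points (A-E) at which a deer whistle was sounded.
#'
#' @return List with `stations` (id, lat, lon) and `references`
#'   (id, lat, lon), decimal degrees.
#' @export
utokyo_fixture <- function() {
  stations <- data.frame(
    id = c("Rec1", "Rec2", "Rec3"),
    lat = parse_dms(c(.dms(35, 39, 38.12, "N"), .dms(35, 39, 36.19, "N"),
                      .dms(35, 39, 37.63, "N"))),
    lon = parse_dms(c(.dms(139, 40, 54.13, "E"), .dms(139, 40, 55.57, "E"),
                      .dms(139, 40, 57.72, "E"))),
    stringsAsFactors = FALSE)
  references <- data.frame(
    id = c("A", "B", "C", "D", "E"),
    lat = parse_dms(c(.dms(35, 39, 37.38, "N"), .dms(35, 39, 36.48, "N"),
                      .dms(35, 39, 37.61, "N"), .dms(35, 39, 37.23, "N"),
                      .dms(35, 39, 37.06, "N"))),
    lon = parse_dms(c(.dms(139, 40, 57.09, "E"), .dms(139, 40, 55.63, "E"),
                      .dms(139, 40, 54.96, "E"), .dms(139, 40, 54.66, "E"),
                      .dms(139, 40, 55.76, "E"))),
    stringsAsFactors = FALSE)
  list(stations = stations, references = references)
}

#' Oze marshland deployment
#'
#' Four recorders spaced within 450 m of one another in the Oze marshland
#' plus five whistle reference points (A-E).  The validation experiment used
#' recorders 1-3; the fourth joined for the wild-deer tracking sessions.
#'
#' @return List with `stations` (4 rows) and `references` (5 rows).
#' @export
oze_fixture <- function() {
  stations <- data.frame(
    id = c("Rec1", "Rec2", "Rec3", "Rec4"),
    lat = parse_dms(c(.dms(36, 56, 31.91, "N"), .dms(36, 56, 34.92, "N"),
                      .dms(36, 56, 23.49, "N"), .dms(36, 56, 27.78, "N"))),
    lon = parse_dms(c(.dms(139, 13, 38.43, "E"), .dms(139, 13, 22.63, "E"),
                      .dms(139, 13, 24.27, "E"), .dms(139, 13, 8.86, "E"))),
    stringsAsFactors = FALSE)
  references <- data.frame(
    id = c("A", "B", "C", "D", "E"),
    lat = parse_dms(c(.dms(36, 56, 38.62, "N"), .dms(36, 56, 30.14, "N"),
                      .dms(36, 56, 28.36, "N"), .dms(36, 56, 30.29, "N"),
                      .dms(36, 56, 19.48, "N"))),
    lon = parse_dms(c(.dms(139, 13, 18.70, "E"), .dms(139, 13, 23.51, "E"),
                      .dms(139, 13, 25.95, "E"), .dms(139, 13, 29.18, "E"),
                      .dms(139, 13, 25.56, "E"))),
    stringsAsFactors = FALSE)
  list(stations = stations, references = references)
}

#' Worked point-E detection times from the playground campaign
#'
#' The manually annotated detection times for the whistle blown at
#' reference point E: first detected at Rec2 at 106.316 s (relative to the
#' recording start), then at Rec1 (106.416 s) and Rec3 (106.417 s), giving
#' lags of 0.100 s and 0.101 s.  Air temperature that day was 18 degrees C
#' and the working sound speed 340 m/s.
#'
#' @return A [detection_set()] with `call_id = "E"`.
#' @export
utokyo_point_e_detections <- function() {
  detection_set("E", c(Rec1 = 106.416, Rec2 = 106.316, Rec3 = 106.417))
}
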