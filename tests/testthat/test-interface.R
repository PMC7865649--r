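ext <- function(f) system.file("extdata", f, package = "tdoatrack")

test_that("station, detection and reference CSVs read with DMS auto-detect", {
  st <- read_stations(ext("stations_utokyo.csv"))
  expect_identical(st$id, c("Rec1", "Rec2", "Rec3"))
  expect_equal(st$lat, utokyo_fixture()$stations$lat, tolerance = 1e-9)
  det <- read_detections(ext("detections_pointE.csv"))
  expect_length(det, 1L)
  expect_identical(det[[1]]$first_station, "Rec2")
  refs <- read_references(ext("references_utokyo.csv"))
  expect_identical(refs$id, c("A", "B", "C", "D", "E"))
})

test_that("malformed input files fail with a named problem", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.csv")
  writeLines(c("call_id,station_id,time_s", "E,Rec1,not_a_number"), bad)
  expect_error(read_detections(bad), "time_s.*not_a_number",
               class = "tdoa_bad_input")
  expect_error(read_stations(file.path(tmp, "absent.csv")), "not found",
               class = "tdoa_bad_input")
  wrong <- file.path(tmp, "wrong.csv")
  writeLines(c("a,b", "1,2"), wrong)
  expect_error(read_stations(wrong), "must have columns",
               class = "tdoa_bad_input")
})

test_that("the localize pipeline writes results, overlays and a snapshot", {
  tmp <- withr::local_tempdir()
  res <- suppressMessages(
    run_localize(ext("stations_utokyo.csv"), ext("detections_pointE.csv"),
                 out_dir = tmp, speed_mps = 340, spacing_m = 4,
                 min_edge_distance_m = 750, verbose = FALSE))
  expect_identical(nrow(res), 1L)
  expect_identical(res$call_id, "E")
  got <- utils::read.csv(file.path(tmp, "results.csv"))
  expect_equal(got$lat, res$lat, tolerance = 1e-9)
  gj <- jsonlite::read_json(file.path(tmp, "results.geojson"))
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, 1L)
  expect_equal(gj$features[[1]]$geometry$coordinates[[1]], res$lon,
               tolerance = 1e-6)
  kml <- readLines(file.path(tmp, "results.kml"))
  expect_true(any(grepl("<Placemark><name>E</name>", kml)))
  snap <- jsonlite::read_json(file.path(tmp, "run_config.json"))
  expect_equal(snap$speed_mps, 340)
  expect_equal(snap$spacing_m, 4)
})

test_that("an empty detections file warns and writes empty results", {
  tmp <- withr::local_tempdir()
  empty <- file.path(tmp, "none.csv")
  writeLines("call_id,station_id,time_s", empty)
  expect_warning(
    res <- run_localize(ext("stations_utokyo.csv"), empty, out_dir = tmp,
                        speed_mps = 340, verbose = FALSE),
    "no detections")
  expect_identical(nrow(res), 0L)
  expect_true(file.exists(file.path(tmp, "results.csv")))
})

test_that("simulation runs are reproducible and round-trip to localization", {
  tmp1 <- withr::local_tempdir(); tmp2 <- withr::local_tempdir()
  cfg <- scenario_config(utokyo_fixture()$stations, timing_noise_sd_s = 0,
                         n_individuals = 2, min_individual_spacing_m = 20,
                         n_intervals = 2, seed = 101)
  run_simulate(cfg, tmp1)
  run_simulate(cfg, tmp2)
  for (f in c("stations.csv", "detections.csv", "truth.csv")) {
    expect_identical(readLines(file.path(tmp1, f)),
                     readLines(file.path(tmp2, f)))
  }
  snap <- jsonlite::read_json(file.path(tmp1, "run_config.json"))
  expect_identical(snap$seed, 101L)
  # simulated files feed straight back into the localizer
  res <- run_localize(file.path(tmp1, "stations.csv"),
                      file.path(tmp1, "detections.csv"), out_dir = tmp1,
                      speed_mps = cfg$speed_mps, spacing_m = 2,
                      min_edge_distance_m = 0, half_extent_m = 150,
                      verbose = FALSE)
  truth <- utils::read.csv(file.path(tmp1, "truth.csv"))
  expect_identical(nrow(res), nrow(truth))
  err <- flat_earth_distance(res$lat, res$lon,
                             truth$lat[match(res$call_id, truth$call_id)],
                             truth$lon[match(res$call_id, truth$call_id)])
  expect_lt(max(err), 2 * sqrt(2))  # noise-free, 2 m lattice
})

test_that("validation reports per-point errors with mean and RMSE", {
  st <- utokyo_fixture()$stations
  refs <- utokyo_fixture()$references
  # a synthetic noise-free whistle at each of two reference points
  det <- lapply(c("C", "E"), function(id) {
    ref <- refs[refs$id == id, ]
    forward_detections(id, ref$lat, ref$lon, st)
  })
  rep <- suppressWarnings(
    run_validate(st, det, refs, speed_mps = 340, spacing_m = 0.5,
                 min_edge_distance_m = 0, half_extent_m = 100))
  expect_identical(rep$n_points, 2L)
  expect_lt(rep$mean_error_m, 0.36)
  expect_gte(rep$rmse_error_m, rep$mean_error_m)
})

test_that("validation flags unmatched ids and a known offset is recovered", {
  st <- utokyo_fixture()$stations
  refs <- utokyo_fixture()$references
  ref_e <- refs[refs$id == "E", ]
  det <- list(forward_detections("E", ref_e$lat, ref_e$lon, st),
              forward_detections("Z", ref_e$lat, ref_e$lon, st))
  expect_warning(
    rep <- run_validate(st, det, refs, speed_mps = 340, spacing_m = 1,
                        min_edge_distance_m = 0, half_extent_m = 100),
    "unmatched")
  expect_identical(rep$per_point$id, "E")
  # single point with a known injected offset: mean = RMSE = offset
  shifted <- local_point(5, 0, ref_e$lat, ref_e$lon)  # 5 m due east
  det5 <- list(forward_detections("E", shifted$lat, shifted$lon, st))
  rep5 <- suppressWarnings(
    run_validate(st, det5, refs, speed_mps = 340, spacing_m = 0.1,
                 min_edge_distance_m = 0, half_extent_m = 60))
  expect_equal(rep5$mean_error_m, 5, tolerance = 0.1)
  expect_equal(rep5$rmse_error_m, rep5$mean_error_m, tolerance = 1e-9)
})

test_that("the tracking pipeline writes clusters, intervals and paths", {
  tmp <- withr::local_tempdir()
  # two individuals: one walking east, one stationary far away
  walk <- local_point((0:5) * 10, rep(0, 6))
  walk$call_id <- sprintf("w%d", 0:5); walk$time_s <- (0:5) * 600 + 30
  still <- local_point(800, 800)
  still$call_id <- "s0"; still$time_s <- 1000
  calls <- rbind(walk, still)
  rep <- run_track(calls, linkage_distance_m = 50, interval_s = 600,
                   session_start = 0, session_end = 3600, out_dir = tmp)
  expect_identical(rep$n_individuals, 2L)
  expect_identical(rep$intervals$n_calls, 7L)
  expect_length(rep$paths, 1L)
  expect_equal(rep$paths[[1]]$net_displacement_m, 50, tolerance = 1e-6)
  expect_true(file.exists(file.path(tmp, "clusters.csv")))
  expect_true(file.exists(file.path(tmp, "interval_counts.csv")))
  gj <- jsonlite::read_json(file.path(tmp, "paths.geojson"))
  expect_length(gj$features, 1L)
  expect_length(gj$features[[1]]$geometry$coordinates, 6L)
})
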