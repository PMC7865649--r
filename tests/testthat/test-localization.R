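test_that("detection sets derive the first detector and non-negative lags", {
  ds <- detection_set("E", c(Rec1 = 106.416, Rec2 = 106.316, Rec3 = 106.417))
  expect_identical(ds$first_station, "Rec2")
  expect_equal(unname(ds$lags[c("Rec1", "Rec3")]), c(0.100, 0.101))
  expect_true(all(ds$lags >= 0))
  expect_true(is_localizable(ds))
  expect_false(is_localizable(detection_set("x", c(Rec1 = 1, Rec2 = 2))))
  expect_error(detection_set("x", c(1, 2, 3)), "named")
  expect_error(detection_set("x", c(Rec1 = 1, Rec1 = 2)), "duplicate")
})

test_that("lag distances are lag times the speed, zero at the first detector", {
  ds <- detection_set("E", c(Rec1 = 0.100, Rec2 = 0, Rec3 = 0.101))
  ld <- lags_to_distances(ds, 340)
  expect_equal(unname(ld$dist_by_station[c("Rec1", "Rec2", "Rec3")]),
               c(34.0, 0, 34.34))
  expect_identical(ld$first_station, "Rec2")

  all0 <- lags_to_distances(detection_set("z", c(a = 5, b = 5, c = 5)), 340)
  expect_equal(unname(all0$dist_by_station), c(0, 0, 0))

  unit <- lags_to_distances(detection_set("u", c(a = 0, b = 1, c = 2)), 331.2)
  expect_equal(unname(unit$dist_by_station[["b"]]), 331.2)

  expect_error(lags_to_distances(detection_set("x", c(a = 1, b = 2)), 340),
               class = "tdoa_insufficient_detections")
  expect_error(lags_to_distances(ds, -10), "positive")
})

test_that("default grids keep the required recorder-to-edge clearance", {
  oze <- oze_fixture()$stations
  g <- build_grid(oze, spacing_m = 5)
  r <- flat_earth_distance(oze$lat, oze$lon, g$center_lat, g$center_lon)
  expect_true(all(g$half_extent_m - r >= g$min_edge_distance_m))
  # half-extent is a whole multiple of the spacing
  expect_equal(g$half_extent_m %% g$spacing_m, 0)
})

test_that("the published 1.6 km / 0.5 m grid has 3201 points per axis", {
  g <- build_grid(utokyo_fixture()$stations, spacing_m = 0.5,
                  half_extent_m = 800)
  expect_identical(g$n_axis, 3201L)
})

test_that("grid construction rejects degenerate and undersized layouts", {
  st <- utokyo_fixture()$stations
  expect_error(build_grid(st[1, ]), ">= 3")
  same <- data.frame(id = c("a", "b", "c"), lat = 35.66, lon = 139.68)
  expect_error(build_grid(same), class = "tdoa_degenerate_geometry")
  line <- local_stations(c(0, 100, 200), c(0, 0, 0))
  expect_warning(build_grid(line, spacing_m = 5), "collinear")
  expect_error(build_grid(st, half_extent_m = 100),
               class = "tdoa_grid_too_small")
})

test_that("candidate at the true source of a noise-free scene has RMSE 0", {
  st <- local_stations(c(0, 300, 0), c(0, 0, 400))
  src <- local_point(60, 80)
  ds <- forward_detections("s", src$lat, src$lon, st)
  ld <- lags_to_distances(ds, 340)
  expect_equal(evaluate_candidate(src$lat, src$lon, st, ld), 0,
               tolerance = 1e-9)
})

test_that("candidates nearest to a non-first recorder are skipped", {
  st <- local_stations(c(0, 300, 0), c(0, 0, 400))
  src <- local_point(10, 10)  # nearest Rec1
  ds <- forward_detections("s", src$lat, src$lon, st)
  ld <- lags_to_distances(ds, 340)
  near2 <- local_point(290, 10)
  expect_true(is.na(evaluate_candidate(near2$lat, near2$lon, st, ld)))
  # with pruning off the same candidate is scored
  expect_false(is.na(evaluate_candidate(near2$lat, near2$lon, st, ld,
                                        prune = FALSE)))
})

test_that("candidate RMSE matches an independent step-by-step calculation", {
  # right-triangle scene: recorders at (0,0), (300,0), (0,400) m; source at
  # (60,80); candidate at (100,100).  Expected value computed by carrying
  # out the projection, distance, lag-distance and RMSE arithmetic directly.
  st <- local_stations(c(0, 300, 0), c(0, 0, 400))
  src <- unlist(local_point(60, 80))
  cand <- unlist(local_point(100, 100))
  fe <- function(p, q) {
    x <- (q["lon"] - p["lon"]) * pi / 180 *
      cos((p["lat"] + q["lat"]) / 2 * pi / 180)
    y <- (q["lat"] - p["lat"]) * pi / 180
    6371000 * sqrt(x^2 + y^2)
  }
  s <- lapply(1:3, function(k) c(lat = st$lat[k], lon = st$lon[k]))
  d_src <- vapply(s, fe, numeric(1), p = src)     # true distances
  obs <- d_src - min(d_src)                       # observed lag distances
  d_cand <- vapply(s, fe, numeric(1), p = cand)
  dmin <- min(d_cand)
  expected <- sqrt(((d_cand[2] - dmin - obs[2])^2 +
                    (d_cand[3] - dmin - obs[3])^2) / 2)
  expect_equal(expected, 61.602662, tolerance = 1e-6)  # frozen

  ds <- forward_detections("s", src[["lat"]], src[["lon"]], st)
  ld <- lags_to_distances(ds, 340)
  got <- evaluate_candidate(cand[["lat"]], cand[["lon"]], st, ld)
  expect_equal(got, expected, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("vectorized candidate evaluation equals the per-point loop", {
  set.seed(31)
  st <- local_stations(c(0, 300, 50), c(0, 40, 400))
  src <- local_point(90, 120)
  ld <- lags_to_distances(
    forward_detections("s", src$lat, src$lon, st), 340)
  pts <- data.frame(x = runif(40, -200, 400), y = runif(40, -200, 500))
  ll <- local_point(pts$x, pts$y)
  vec <- evaluate_candidate(ll$lat, ll$lon, st, ld, tie_tol_m = 0.5)
  one <- vapply(seq_len(nrow(ll)), function(i) {
    evaluate_candidate(ll$lat[i], ll$lon[i], st, ld, tie_tol_m = 0.5)
  }, numeric(1))
  expect_equal(vec, one)
})

test_that("noise-free sources inside the array are recovered to the lattice", {
  # quantization along a poorly constrained direction can exceed half the
  # lattice diagonal by the conditioning of the two lag-distance
  # constraints, so the bound carries that factor
  set.seed(42)
  st <- utokyo_fixture()$stations
  src <- sample_in_triangle_clear(8, st)
  for (k in 1:8) {
    ds <- forward_detections(paste0("s", k), src$lat[k], src$lon[k], st)
    r <- localize_small(ds, st, half_extent_m = 100, spacing_m = 0.5)
    err <- flat_earth_distance(r$lat, r$lon, src$lat[k], src$lon[k])
    bound <- lattice_error_bound(src$lat[k], src$lon[k], st,
                                 ds$first_station, 0.5)
    expect_lt(err, bound + 0.05)
    expect_lte(r$rmse_m, 1)
  }
})

test_that("all-zero lags retrieve the circumcenter of an equilateral array", {
  side <- 200
  st <- local_stations(c(0, side, side / 2),
                       c(0, 0, side * sqrt(3) / 2))
  ds <- detection_set("c", c(Rec1 = 1, Rec2 = 1, Rec3 = 1))
  r <- localize_small(ds, st, half_extent_m = 150, spacing_m = 1)
  cc <- local_point(side / 2, side / (2 * sqrt(3)))  # circumcenter
  expect_lt(flat_earth_distance(r$lat, r$lon, cc$lat, cc$lon),
            sqrt(2) + 1e-6)  # within one lattice step
})

test_that("retrieved positions are invariant to station relabeling", {
  set.seed(5)
  st <- utokyo_fixture()$stations
  src <- sample_in_triangle(1, st)
  ds <- forward_detections("s", src$lat, src$lon, st, noise_sd = 0.01)
  r1 <- localize_small(ds, st, half_extent_m = 100, spacing_m = 1)
  perm <- c(Rec1 = "B", Rec2 = "C", Rec3 = "A")
  st2 <- st; st2$id <- unname(perm[st$id])
  times2 <- ds$times; names(times2) <- unname(perm[names(ds$times)])
  r2 <- localize_small(detection_set("s", times2), st2,
                       half_extent_m = 100, spacing_m = 1)
  expect_equal(r1$lat, r2$lat)
  expect_equal(r1$lon, r2$lon)
  expect_equal(r1$rmse_m, r2$rmse_m)
})

test_that("with four recorders both station policies localize the call", {
  set.seed(9)
  oze <- oze_fixture()$stations
  src <- sample_in_triangle(1, oze)
  ds <- forward_detections("q", src$lat, src$lon, oze)
  expect_identical(ds$n_stations, 4L)
  r_early <- localize(ds, oze, speed_mps = 340, spacing_m = 2,
                      min_edge_distance_m = 0, half_extent_m = 400,
                      station_policy = "earliest")
  r_best <- localize(ds, oze, speed_mps = 340, spacing_m = 2,
                     min_edge_distance_m = 0, half_extent_m = 400,
                     station_policy = "best_triple")
  expect_identical(r_early$n_stations_used, 3L)
  expect_identical(r_best$n_stations_used, 3L)
  expect_lt(flat_earth_distance(r_early$lat, r_early$lon, src$lat, src$lon),
            3)
  expect_lt(flat_earth_distance(r_best$lat, r_best$lon, src$lat, src$lon), 3)
  expect_lte(r_best$rmse_m, r_early$rmse_m + 1e-9)
})

test_that("batch localization preserves order and reports failures", {
  st <- utokyo_fixture()$stations
  expect_identical(localize_batch(list(), st), list())
  src <- sample_in_triangle(2, st)
  good1 <- forward_detections("a", src$lat[1], src$lon[1], st)
  bad <- detection_set("b", c(Rec1 = 1, Rec2 = 1.01))  # too few stations
  good2 <- forward_detections("c", src$lat[2], src$lon[2], st)
  out <- localize_batch(list(good1, bad, good2), st, speed_mps = 340,
                        spacing_m = 1, min_edge_distance_m = 0,
                        half_extent_m = 100)
  expect_length(out, 3L)
  expect_s3_class(out[[1]], "localization_result")
  expect_s3_class(out[[2]], "localization_failure")
  expect_s3_class(out[[3]], "localization_result")
  expect_identical(vapply(out, function(x) x$call_id, character(1)),
                   c("a", "b", "c"))
  expect_warning(tab <- results_table(out), "failed")
  expect_identical(nrow(tab), 2L)

  single <- localize_batch(list(good1), st, speed_mps = 340, spacing_m = 1,
                           min_edge_distance_m = 0, half_extent_m = 100)
  expect_length(single, 1L)
  expect_equal(single[[1]]$lat, out[[1]]$lat)
})
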