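# tdoatrack

Passive acoustic monitoring can tell you *that* a deer called; `tdoatrack`
tells you *where*. The package localizes calling animals from the time
lags at which three or more synchronized, stationary sound recorders
detect the same call, and turns the localized calls into ecology: counts
corrected for repetitive calling by the same territorial individual, and
movement paths. It is aimed at wildlife surveys in terrain where spotlight
counts, camera traps and drones struggle — open marshland, muddy wetland,
rugged ground — and at anyone with a recorder array and a table of
annotated call-detection times.

## The method

The absolute emission time of a call is unknown, so only time *differences*
carry information. With the first-detecting recorder as reference, each
other recorder's lag `T_k` converts to a lag distance

```
D_k = T_k × V        (V = speed of sound; 331.2 + 0.606·T °C m/s, or fixed)
```

which places the source on a hyperbola branch. The source position is
retrieved by exhaustive trial and error over a square lattice (default
spacing 0.5 m, recorder-to-edge clearance ≥ 750 m): for each candidate
`x`, compute flat-earth distances to the recorders, subtract the distance
to the nearest one to get candidate lag distances `D*_k(x)`, and score

```
RMSE(x) = sqrt( ((D*_1 − D_1)² + (D*_2 − D_2)²) / 2 )
```

Candidates whose nearest recorder is not the observed first detector are
skipped. The lattice point with minimum RMSE is the retrieved position.
Distances use the equirectangular approximation
`d = R·sqrt((Δλ·cos φ̄)² + Δφ²)` on a 6,371,000 m sphere — accurate to well
under 0.1% at array scales (tested against a haversine oracle).

On top of the localizer sit a forward simulator (propagation delay +
Gaussian annotation-timing noise + distance-dependent audibility
censoring), single-linkage clustering that collapses calls within 50 m into
one territorial individual, per-interval call statistics, and movement-path
summaries. I/O is plain CSV, GeoJSON and KML.

## Worked example

The built-in playground fixture ships three recorder positions and five
surveyed whistle points. At reference point E the call was first detected
at Rec2, then 0.100 s later at Rec1 and 0.101 s later at Rec3; the session
ran at 340 m/s. Localizing on the published 1.6 km × 1.6 km, 0.5 m grid:

```r
library(tdoatrack)
fx <- utokyo_fixture()
r  <- localize(utokyo_point_e_detections(), fx$stations,
               speed_mps = 340, spacing_m = 0.5, half_extent_m = 800)
r
#> <localization_result> call E: 35.660243, 139.682141 (RMSE 0.26 m)
#>   first detector Rec2; 3 stations; 2,933,501 candidates evaluated
E <- fx$references[fx$references$id == "E", ]
flat_earth_distance(r$lat, r$lon, E$lat, E$lon)
#> 5.83 m from the surveyed point
```

The 0.26 m objective value says the lags are mutually consistent to about
a quarter meter at the retrieved point; the 5.83 m offset from the
surveyed position corresponds to ~0.017 s of annotation-timing error at
340 m/s — the practical accuracy ceiling of hand-annotated onsets.

A full synthetic session and its ecology layer:

```r
cfg <- scenario_config(oze_fixture()$stations, seed = 42)
sim <- simulate_calls(cfg)
tr  <- run_track(sim$truth, linkage_distance_m = 50, interval_s = 600,
                 session_start = 0, session_end = 7200)
tr
#> <tracking_report> 75 call(s) -> 3 individual(s); mean 6.25 calls/interval
```

Seventy-five raw calls collapse to the three simulated stags — the
repetitive-call correction that makes acoustic counting honest.

Command-line use mirrors the R surface:

```sh
Rscript inst/cli/tdoatrack.R localize \
  --stations inst/extdata/stations_utokyo.csv \
  --detections inst/extdata/detections_pointE.csv \
  --out out/ --speed 340
```

with subcommands `localize`, `simulate`, `validate` (per-point error, mean
and RMSE against surveyed references) and `track`.

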