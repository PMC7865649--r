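---
title: "Grid-search TDOA localization of animal calls: model, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-search TDOA localization of animal calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tdoatrack)
```

## The estimation problem

A calling animal (the motivating case is a rutting sika deer stag) emits a
sound at an unknown position and an unknown time. Three synchronized,
stationary recorders with surveyed positions detect the call at times that
differ by the differences in propagation distance. The absolute travel time
to the nearest recorder is unobservable, so the data reduce to the identity
of the **first detector** and the **time lags** of the other recorders
relative to it. Each lag, multiplied by the speed of sound `V`, is a *lag
distance*

$$D_k = T_k \times V,$$

which constrains the source to one branch of a hyperbola with the first
detector and recorder `k` as foci. With three recorders there are two lags,
and the source lies at an intersection of two hyperbola branches.

`tdoatrack` retrieves that intersection the way the field method defines
it: by exhaustive trial and error over a square lattice of candidate
positions. For a candidate `x` the distances to the three recorders
$D^{inv}_k(x)$ are computed, the nearest recorder identified
($D^{min}(x)$), and the candidate lag distances formed as
$D^*_k(x) = D^{inv}_k(x) - D^{min}(x)$ for the two non-nearest recorders.
The objective is the RMSE over the two matched pairs,

$$\mathrm{RMSE}(x) = \sqrt{\tfrac{1}{2}\left[(D^*_1(x) - D_1)^2 +
  (D^*_2(x) - D_2)^2\right]},$$

and the retrieved position is the lattice point with the minimum RMSE.
Candidates whose nearest recorder is not the observed first detector are
skipped; this prunes the search to the first detector's nearest-recorder
region and is how the method avoids wasting work on geometrically
impossible cells (`prune = FALSE` disables it for cross-checks, and the
pruned and exhaustive searches agree whenever the exhaustive argmin lies in
that region — a tested invariant).

Two printed forms of these equations circulate with typographical slips; the
package implements the only readings that define a metric and an RMSE: the
north–south term of the planar distance is the latitude **difference**
(paired with the mean-latitude cosine on the east–west term), and the RMSE
pairs each $D^*_k$ with its own $D_k$. The localization log notes both
corrections once per run.

## Geometry

All distances use the flat-earth (equirectangular) approximation on a
sphere of radius 6,371,000 m:

$$d = R\sqrt{x^2 + y^2},\qquad
  x = \Delta\lambda\cos\bar\varphi,\qquad y = \Delta\varphi,$$

with angles in radians and $\bar\varphi$ the mean latitude of the pair.
Over the deployments this package targets (arrays a few hundred meters
across, grids up to a few kilometers) it agrees with the haversine
great-circle distance to well under 0.1% — a tested invariant against an
independent haversine oracle. No ellipsoidal geodesy is attempted; the
flat-earth form *is* the normative computation. Coordinates are accepted as
decimal degrees or DMS strings (`35°39′38.12″ N`), auto-detected per cell.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `spacing_m` | 0.5 | m | lattice tolerance of the published method |
| `min_edge_distance_m` | 750 | m | recorder-to-grid-edge clearance so the grid covers any detectable source |
| `half_extent_m` | auto | m | auto = max station–centroid distance + edge clearance; override to reproduce published 1.6 km / 3 km grids |
| `speed_mps` / `temperature_c` | — | m/s, °C | explicit speed always wins; else `v = 331.2 + 0.606 T`, anchored at 331.2 (0 °C) and 343.3 ≈ 343 (20 °C) |
| `tie_tol_m` | one spacing | m | nearest-recorder ties at region boundaries count as matching, so near-zero-lag sources are not spuriously skipped |
| `timing_noise_sd_s` | 0.018 | s | human precision of annotating a call onset on a spectrogram |
| `detection_range_m` | 450 | m | deployment spacing chosen so calls reach three recorders |
| `linkage_distance_m` | 50 | m | calls within this distance are attributed to one territorial male |
| `min_individual_spacing_m` | 100 | m | simulator territoriality floor between stags |

The sound-speed model is the standard linear dry-air approximation; it is
only a convenience, and a field-fixed value (e.g., 340 m/s on an 18 °C
evening) passed as `speed_mps` overrides it unconditionally.

## The forward simulator

`simulate_calls()` emulates the detection-time level of a monitoring
session: callers are placed in the arena respecting the territorial
spacing, walk a Gaussian step per interval (default 10 m SD), and emit
Poisson numbers of calls per interval. A call's detection time at station
`k` is `emission + distance/V + N(0, timing_noise_sd_s)`, and stations are
censored by an audibility model — a sharp 450 m cutoff by default, or a
three-state model (certain ≤ 423 m, probability 0.5 up to 545 m, never
beyond) patterned on a field audibility trial; the 0.5 is a modeling
interpolation of "barely detected", not a measured rate. Timing noise is
Gaussian and independent across stations because nothing richer is known
about annotation error; it is configurable. Session defaults (twelve
10-minute intervals, three callers at two calls each per interval) make
total call counts concentrate near 72, matching the scale of a published
two-hour rutting-season session.

The simulator deliberately omits: waveforms and spectrograms (detection
times are the unit of analysis), anisotropic propagation, wind/humidity
effects (excluded from the method's scope), correlated annotation errors,
and caller motion *within* an interval. Tests that pass on simulated data
therefore certify the geometry and search machinery, not the hard part of
real fieldwork — deciding call onsets in noisy recordings.

## Numerical choices

- **Grid anchoring.** The lattice is centered on the station centroid with
  axes locally east/north; the published experiments do not state their
  grid placement, so reproduction of a published retrieval error carries a
  grid-phase uncertainty of order one lattice diagonal. The package's
  tolerance for the headline point-E figure (±1.5 m around 6.17 m) absorbs
  this plus DMS coordinate rounding (0.01″ ≈ 0.3 m).
- **Tie-breaking.** Equal minimum RMSE resolves to the first candidate in
  scan order: south-to-north rows, west-to-east within a row.
  Deterministic and documented rather than randomized.
- **Vectorization.** The lattice is evaluated as whole-vector arithmetic
  (≈10.2 M candidates for the 1.6 km grid run in seconds); a tested
  contract keeps it identical to the per-point loop.
- **More than three recorders.** The method is defined for three. With
  four or more detecting stations the default policy keeps the three
  earliest detectors; a `best_triple` policy evaluates every 3-subset and
  keeps the lowest-RMSE result. Both are labeled heuristics — the published
  four-recorder deployment does not state its rule.
- **Interval SD convention.** Published per-interval call statistics do not
  state population vs sample SD and the underlying counts are unpublished,
  so both conventions are exposed (`sd_type`), population by default, and
  no SD figure is treated as a reproduction target.
- **Time gating.** Clustering is purely spatial by default because
  territorial stags re-call from the same area tens of minutes apart; an
  optional `max_time_gap_s` gate exists for denser populations.

## Known limitations

- **Lattice quantization is inflated by constraint conditioning.** The
  argmin of the RMSE over the lattice is *not* always the lattice point
  nearest the true source. The two lag-distance constraints have Jacobian
  rows $u_k - u_{first}$ (unit vectors from the source); where the smaller
  singular value is below 1 the half-diagonal quantization bound
  (0.5·spacing·√2 ≈ 0.36 m at 0.5 m spacing) stretches by the condition
  number. On both built-in arrays roughly nine of ten noise-free in-triangle
  sources land within 0.36 m and the rest within the conditioning-scaled
  bound (≈0.5 m); the test suite asserts the conditioning-aware bound.
- **Ghost intersections.** Two hyperbola branches can intersect twice. For
  sources within ~10 m of a recorder the second intersection can sit tens
  of meters away with a *lower* lattice RMSE — an intrinsic three-receiver
  TDOA ambiguity that the minimum-RMSE rule cannot break. A fourth
  recorder (via `best_triple`) or a detection-range plausibility check is
  the practical remedy.
- **Outside the array accuracy degrades** (the constraints become nearly
  parallel), consistent with the published inner- vs outer-point error gap.
- Station positions, clock synchronization and the assumed sound speed
  enter the error budget directly; 1 m of station survey error or ~0.5% of
  speed error is of the same order as the published retrieval errors.

## Problem sizes in the shipped tests

The test suite validates the full-resolution 1.6 km × 1.6 km, 0.5 m grid
once (the headline point-E reproduction, ≈10.2 M candidates), and runs its
statistical sweeps on reduced grids chosen to keep each property
informative: 100 noise-free sources per array at 0.5 m spacing on
triangle-sized grids, 1000 noisy scenes (σ = 0.018 s) at 0.5 m spacing on
a 300 m grid, 100 pruning-equivalence scenes at 5 m spacing, and a
four-level noise sweep (σ ∈ {0, 0.01, 0.02, 0.05} s, 150 scenes each) at
1 m spacing. These sizes are the package's own trade-off between sweep
breadth and a test suite that runs in a couple of minutes.
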