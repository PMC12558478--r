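---
title: "Methods: from building damage models to facility damage reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from building damage models to facility damage reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facdamage)
```

## The problem

After a major earthquake, response planners need to know which hospitals,
dialysis centers and pharmacies are damaged, and they need to know it in
days, not the weeks a ground survey takes. Convolutional models run on
post-event satellite imagery can estimate damage per building, but their
outputs arrive in incompatible dialects. `facdamage` works with the two
dialects in operational use after the February 2023 earthquakes in southern
Türkiye:

* **polygon dialect** (`DamagePolygon`): one footprint polygon per building
  with the *fraction* of the footprint estimated to belong to a damaged
  building;
* **centroid dialect** (`DamageCentroid`): one point per building with a
  *binary* damage class (1 = major damage or destroyed), the continuous
  score having been thresholded per city by the model developers. That
  score threshold is taken as given; re-deriving it is out of scope.

Neither dialect mentions health facilities. The package's job is the
translation: building-level estimates in, a per-facility damage report out,
with honest uncertainty attached.

## Decision rules

Both dialects are first reduced to a binary *damaged building* definition:
a polygon building is damaged when its damaged fraction strictly exceeds
0.40; a centroid building is damaged when its class is 1. The 40% cut, the
25 m radius and the third-quartile rule below are the operational values
used in the field for this task; all of them live in a single
`thresholds()` object and every inequality is strict, so boundary cases are
reproducible.

**Individual method.** A facility is damaged when its point intersects a
damaged polygon, *or* lies strictly within 25 m of the centroid of a
damaged building (the *rescue radius*, which catches facility points
geocoded just off their building). For the centroid dialect, where
"intersection" between two point sets is undefined, the facility takes the
class of its nearest centroid provided it is within the same 25 m radius —
a documented choice of this package, configurable separately
(`centroid_radius_m`). Facilities with no building object within reach are
reported undamaged and flagged `no_data`; by default the pipeline excludes
facilities flagged `no_data` by either model before computing any summary,
mirroring how the original analysis excluded facilities lacking coverage
from both models (set `exclude_no_data = FALSE` to retain them).

**Aggregated method.** All buildings of one model are binned into
flat-topped regular hexagons of 0.125 km^2 (edge
$a = \sqrt{2A/(3\sqrt3)} \approx 219.3$ m), anchored at the lower-left
corner of the data's bounding box. Cell assignment is Voronoi assignment to
the nearest hexagon centre, which for a hexagonal lattice *is*
point-in-hexagon; boundary ties go to the lowest cell id. Each non-empty
cell gets a damaged proportion; empty cells are excluded from all
quantiles, because a quartile over undefined values is meaningless. The
quartile breaks use linear interpolation between order statistics
(`stats::quantile` type 7) — the estimator is configurable
(`quantile_type`) because the Q3 break sits directly in the decision rule.
A facility is *likely damaged* when its cell's proportion strictly exceeds
Q3. Hexagons (not squares) were chosen because published renderings of
this analysis use hexagonal cells; square cells can be obtained by
swapping the grid constructor. Quartiles are computed per run, i.e. per
city when cities are run separately — which is the intended usage, since
damage fields and building stocks differ by city. Note the interpolated
estimator's discretization: with $n$ non-empty cells up to
$0.25n + 0.75$ of them can fall strictly above the Q3 break, slightly more
than a quarter.

**Evaluation.** Model agreement uses Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$ with the asymptotic standard error
$\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ for its interval (a bootstrap alternative
is provided; published intervals for this statistic rarely state their
method, so none is asserted anywhere in the package). When both raters are
constant, kappa is reported as flagged-undefined, never silently 0 or 1.
Accuracy against gold labels uses sensitivity and specificity with *exact*
Clopper–Pearson intervals via the beta-quantile identity; the exact family
was chosen because every printed interval in the motivating analysis
matches it at the stated integer counts, which the test suite verifies
against an independent tail-probability bisection oracle. Zero
denominators flag the estimate as undefined rather than erroring, because
strata like "dialysis centers with gold-positive labels" are legitimately
empty in small samples.

## Coordinates

"25 meters" and "0.125 km^2" only mean something in a metric plane, so all
spatial logic runs in projected meters. Inputs in WGS84 are projected with
a local tangent projection: degrees of longitude and latitude scaled by the
WGS84 prime-vertical and meridian radii of curvature at the projection
origin (the data centroid by default). At city scale this is
distance-faithful to well under 0.1% — the tests hold it to a geodesic
oracle — and it inverts exactly, which a full UTM series does not need to
do any better for this purpose. Coordinates more than a degree from the
origin trigger a warning.

Because no GDAL bindings are required anywhere, the readers accept GeoJSON
and CSV; GeoPackage inputs must be converted first (`ogr2ogr -f GeoJSON`).
Self-intersecting footprint rings are repaired by splitting at each
crossing into simple lobes (the planar equivalent of a zero-width buffer);
irreparable zero-area geometries are rejected and logged, and every input
record is either returned or logged, never dropped silently.

## The synthetic city

Real deposited damage datasets are large and partly proprietary, so the
generator builds cities with the same *error anatomy* instead, and every
downstream stage is tested against them.

* **Stock.** Axis-aligned rectangular footprints: dense blocks (tight
  grids of equal small squares with 2.5–4.5 m gaps, below the 6 m polygon
  merge distance) and sparse buildings (centroids ≥ 52 m apart, a share of
  them large enough to host hospitals). Defaults: 800 buildings on a
  2 × 2 km city, half of them dense.
* **Damage field.** `clamp(exp(-d/d0) + N(0, noise_sd), 0, 1)` with
  `d0 = 500` m, chosen so roughly the central sixth of the city exceeds
  the 40% cut — damage rates of the order seen in the motivating analysis.
  Dense-zone buildings evaluate the decay at their *block centre* rather
  than their own centroid: city blocks collapse together, and this
  block-level coherence is also what makes error-free recovery exact (see
  below). Buildings at fraction ≥ 0.8 are flagged *destroyed* — the
  simulator's stand-in for structures indistinguishable from rubble.
* **Facilities.** Hospitals on large buildings, pharmacies preferentially
  in dense blocks, dialysis centers on sparse small buildings; point =
  host centroid + Gaussian geocoding jitter (default σ = 3 m), displaced
  1–5 m outside the footprint with probability 0.06. Gold label = host's
  true fraction > 0.40. Default counts per city (8 hospitals, 4 dialysis,
  150 pharmacies) scale the motivating study's three-city sample
  (25/13/454) down to one city.
* **Error modes** (`error_params()`), with defaults read off the observed
  error tallies of a 50-facility imagery review (13 merge errors, 8
  multi-centroid, 6 destroyed-miss, 3 geocoded-outside): with probability
  `p_merge` an adjacent dense pair is emitted as one merged polygon whose
  fraction is the *area-weighted mean* — reproducing exactly the dilution
  that makes a damaged small building disappear inside a big polygon; with
  probability `p_multi_centroid` a large building emits 2–3 centroids
  (uniform on {2, 3}; no distribution is documented anywhere, so the
  smallest plausible one), one per equal-width wing, each classified from
  its wing sub-fraction, with the building's damage concentrated from the
  first wing on (wing $j$ gets $\mathrm{clamp}(kf - (j-1), 0, 1)$, which
  preserves the building mean and makes "one damaged wing of three" an
  exact construction); with probability `p_destroyed_miss` a destroyed
  building is emitted as near-undamaged (fraction uniform on [0, 0.2], or
  class 0) — the error mode that dominated sensitivity loss in practice.

Everything is deterministic given the master seed (per-stage sub-seeds are
derived from it), and a city's provenance block regenerates it
bit-for-bit.

**What the generator does not emulate:** real building outlines,
multi-polygon complexes, street networks, the spatial correlation of model
errors with imagery acquisition geometry, and systematic between-city
differences in urban form. Passing tests on synthetic cities therefore
demonstrate that the *pipeline logic* is correct under the documented
error modes, not that any given model reaches a particular accuracy on
real imagery.

## Why error-free recovery needs a noise-free field

With all error probabilities zero and zero jitter, both dialects' outputs
equal thresholded truth and each facility sits on its host's centroid, so
individual overlay should recover gold labels exactly — and the tests
require sensitivity = specificity = 1. One subtlety: the recovery
configuration also sets `noise_sd = 0`. With per-building field noise a
dense block can straddle the 40% cut, and then the 25 m rescue rule itself
marks a facility damaged because its *neighbour's* centroid is damaged —
a false positive produced by a perfectly faithful model. That is a real
property of the rescue rule worth knowing about, not a model error, so it
is kept out of the error-free recovery definition.

## Problem sizes and numerical choices

The test-suite and acceptance runs use cities of 120–400 buildings with
20–60 facilities, 20 seeds for exhaustive oracle-equivalence checks
(spatial queries against brute-force all-pairs implementations), 100 seeds
for the destroyed-miss degradation sweep, and 2,000 simulated draws per
(p, n) point for interval coverage; these sizes give stable Monte-Carlo
estimates while keeping a full run in the low minutes. Quantile and
interval computations delegate to `stats::quantile` and `stats::qbeta`;
geometry predicates use an epsilon of 1e-9 (relative) for on-edge tests
and exact comparisons elsewhere; distance ties in nearest-centroid matching
break by lowest building id so runs are order-independent, and shuffling
any input leaves every call unchanged.

## A worked synthetic run

```{r example, eval = FALSE}
cfg <- run_config(
  synthetic = list(n_buildings = 500,
                   counts = c(hospital = 6, dialysis = 3, pharmacy = 60)),
  out_dir = "report", seed = 11)
res <- run_pipeline(cfg)
res$report            # per-city/type damage table, both models
res$metrics$individual
res$metrics$aggregated
```

The bundle written to `out_dir` contains the per-facility calls, the
summary table, per-method metrics, the classified hexagonal grids as
GeoJSON choropleth layers, and a provenance file sufficient to reproduce
the run exactly.

## Known limitations

* The aggregated method estimates the probability that a facility stands
  in a heavily damaged *area*; it is not an estimate of damage to the
  facility itself.
* Kappa's asymptotic interval is unreliable for very small strata; the
  bootstrap option helps, and singleton strata report kappa as undefined.
* The local tangent projection is for city-scale analyses; continental
  extents need a proper projected CRS upstream.
* The polygon repair handles self-crossings; it does not attempt to fix
  unclosed rings or collapse duplicate vertices beyond what the area test
  rejects.
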