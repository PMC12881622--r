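---
title: "Mapping forest loss from multi-date multispectral stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest loss from multi-date multispectral stacks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestchange)
```

## The problem and the approach

`forestchange` maps year-to-year forest loss from Sentinel-2-like surface
reflectance. The workflow has two halves. First, a baseline land-cover map is
built for a reference year by a two-stage random-forest classification:
forest against non-forest, then dominant leaf type (coniferous against
broadleaved) inside the forest mask. Second, loss between two consecutive
years is detected by *direct classification of change*: a single 100-tree
random forest labels every forest pixel as unchanged, converted from woody to
non-woody cover (clear cuts, logging, other non-fire damage), or burnt,
using the stacked evidence of both years.

The change features are the ten bands of each year's June--August median
mosaic plus two index differences, 22 features per pixel. The indices are
the standard normalized differences

$$\mathrm{NDVI} = \frac{B8 - B4}{B8 + B4}, \qquad
  \mathrm{NBR} = \frac{B8 - B12}{B8 + B12},$$

differenced as $t_1 - t_2$ so that vegetation loss is positive. NBR collapses
after fire (NIR drops, SWIR2 rises) while NDVI collapses after any removal of
green canopy, which is what lets one classifier separate burnt from cleared
forest.

Because no imagery ships with the package, a synthetic-scene generator
produces the study conditions: multi-date 10-band acquisitions with cloud
gaps, a noisy mock land-cover reference product, and injected clearing and
burn events with exact truth. Every downstream stage is tested against that
truth.

## The synthetic scenes: what they emulate and what they do not

A scene is a Voronoi patchwork of the eight mapped classes (coniferous,
broadleaved, sealed, grassland, cropland, bare soil, wetland, water). Each
acquisition is simulated per pixel as

$$x_b = \mu_{c,b} + a_{c,b}\,\sin\!\big(2\pi(\mathrm{doy} - 81)/365\big) + \varepsilon_b,
  \qquad \varepsilon_b \sim N(0, \sigma^2),$$

with class-mean reflectances $\mu$, a small seasonal sinusoid peaking near
the summer solstice, and independent Gaussian pixel noise, clamped to
$[0,1]$. The default signature library uses plausible growing-season surface
reflectances; the defaults that matter:

* `noise_sd = 0.008` per band. Every pair of class signatures is separated
  by at least three noise SDs in at least one band, so classes are
  recoverable but single-band thresholds are not trivially perfect.
* `seasonal_amplitude = 0.01` on vegetated classes, zero on sealed, water
  and disturbance surfaces. Multi-date stacks therefore carry a real (if
  modest) phenological signal.
* Burn surfaces have lower B8 and higher B12 than either woody class, so
  NBR strictly drops after every burn; cleared surfaces have bare-soil-like
  spectra with NDVI far below the woody classes.
* `cloud_fraction = 0.05` per acquisition, realised as random rectangles —
  real clouds are not rectangular, but rectangles make mask arithmetic
  exactly testable.
* Acquisitions default to days 105, 135, 166, 196 and 227 (mid-April to
  mid-August), matching a 3--5 image per season selection. Classification
  uses the April--September window; change mosaics the June--August window.
* Change events are polygons (rectangles in practice) applied to all
  acquisitions from the event year onward; the generator refuses events that
  overlap non-woody truth, because such a truth map would be inconsistent.

The mock reference product is the year-1 truth degraded by `label_noise_rate
= 0.25`, emulating the roughly 75% overall accuracy reported for global
land-cover products. Noise is applied in 9 × 9-pixel patches — the footprint
of one pixel of a 100 m product on the 10 m grid — rather than as
independent pixel flips, because product errors are spatially coherent.
Exactly `round(rate * n)` pixels are relabelled, so the contract is exact
under test.

The generator does **not** model mixed pixels, topography, BRDF effects,
atmospheric residuals, georegistration error, or gradual degradation. A
passing recovery test therefore demonstrates that the pipeline's logic is
sound under clean class-conditional statistics — not that the accuracies
would transfer to real imagery, where signatures overlap far more.

## Reference sampling and automatic verification

Sampling from the (noisy) reference raster follows three rules: a 10 m
internal buffer (morphological erosion, one pixel at 10 m) keeps points off
class edges; a 20 m minimum distance is enforced between all accepted points
across classes (the stricter of the two possible readings); and a per-class
density cap of `density` points per km² of (eroded) class area. Rejection
sampling gives up on a class after 100 times its target count, preventing
non-termination under dense constraints.

Each point carries three attributes: land-cover class, forest flag, leaf
type. Points are then screened spectrally: per class, the per-band median
and MAD of the candidate spectra are computed, and a point is dropped when
it leaves the median ± 3 × 1.4826 × MAD band in more than three of the ten
bands. The rule is robust (median/MAD), parameter-light and exactly
testable; classes with fewer than ten candidates pass through unverified
since robust scale estimates would be meaningless. Under 25% patchy label
noise this screen demonstrably reduces the mislabelled fraction, which is
asserted as a property test against synthetic truth.

The default density of 2 points/km² mirrors the operational rule for
full-size scenes. On the small test scenes used throughout (0.2--6.6 km²
instead of thousands), that rule would leave a handful of points per class,
so the bundled pipeline runs use 50 points/km²: the point *counts* per class
(tens to a few hundred) are then proportionate to what the operational rule
yields on real granules. This is a deliberate scaling choice of the test
conditions, stated once here; the sampling-rule defaults themselves are
unchanged and are what the constraint suite asserts.

## Classification, transfer, and what the accuracies mean

All three classifiers are seeded 100-tree random forests (`ranger`,
single-threaded for bit-reproducibility) with the conventional √p candidate
features per split and unlimited depth. The 60/40 per-class split applies to
the cover and leaf models, 7:3 to the change model. Two accuracies are
reported and never conflated: the *model* (validation-split) accuracy, and
the *map* accuracy against independent truth via stratified verification
polygons. The latter uses 100 polygons of 10 × 10 m per class, drawn after
shrinking each class region 10 m inward; at 10 m resolution each polygon is
exactly one pixel, and its reference label is the synthetic truth at that
pixel.

Cross-scene or cross-period *transfer* means applying a fitted model
unchanged to another scene's feature stack after a strict schema check; the
pipeline trains its models on the first configured region and transfers the
change model to the rest, mirroring the operational regime where a model
trained on one region serves several.

## Change detection numerics

* **Difference orientation.** Differences are $t_1 - t_2$, so loss is
  positive, and the candidate threshold is one-sided on the loss side —
  the mask exists to find potential loss, not gain.
* **Candidate mask.** A pixel is a candidate when its dNDVI or dNBR exceeds
  the domain mean + k·SD (k = 3 by default), statistics computed over valid
  pixels of the year-1 forest mask. The union rule is the default because it
  maximises candidate recall for reference-area collection; intersection is
  a config option. A zero-variance domain yields an empty mask by
  convention. The mask proposes reference areas; it does not gate the
  classifier, which labels every in-mask pixel.
* **Minimum mapping unit.** Connected components of a change class with
  area ≤ 400 m² (4 pixels at 10 m) revert to "no change". Components use
  8-connectivity, which favours keeping fragmented burn scars; filtered
  pixels revert to no-change rather than nodata so the map stays complete.
  The filter is idempotent and is tested against an independent flood-fill
  oracle, with the 4-pixel/5-pixel boundary asserted exactly.
* **Median convention.** Mosaics use the median of unmasked observations;
  with an even count, the mean of the two middle values. A mosaic pixel is
  valid iff at least one observation contributed.
* **Zero denominators.** Normalized differences are nodata where the band
  sum is zero; index values are nodata wherever any input band is invalid.
* **Reference areas.** Operationally these are digitised manually; here they
  come from config polygons, or from synthetic truth via
  `reference_areas_from_truth()`, which takes the largest inscribed square
  of each class component (found from the erosion depth) so that a
  reference rectangle can never swallow a hole belonging to another class.
  Their 4--400 ha typical size range is soft-checked with a warning only,
  since miniature test scenes legitimately fall below it.

## Accuracy assessment

The error matrix counts (map class, reference class) pairs, rows = map.
From it: overall accuracy (trace/n), per-class user's and producer's
accuracy, per-class F1, and Cohen's kappa with expected agreement
$p_e = \sum_i r_i c_i / n^2$. F1 is implemented as the harmonic mean of UA
and PA — the standard definition. Empty rows or columns yield `NA` metrics,
never zero, so an absent class cannot masquerade as a failing one. All
closed forms are cross-checked against brute-force recomputation from raw
label pairs.

## Regional reporting and rounding

Pixel counts convert to hectares as count × pixel² / 10⁴ (100 pixels = 1 ha
at 10 m). Per-period class shares and cover percentages are rounded
*half-up* at the printed precision (whole percent for shares, 0.1 for cover
fractions), because that is how such tables are conventionally printed;
unrounded values are kept alongside in `*_raw` columns. Shares of a zero
total are `NA`, reported as undefined. Pooled totals are sums of the
regional totals computed from the same operands, so additivity is exact.
The package ships a per-region loss table
(`regional_loss_table()`) as the worked-example input for the aggregation;
one pair of its Lviv cells is typographically ambiguous in the original
source, and the shipped values use the only reading consistent with the
printed pooled totals and the Lviv class shares.

## Problem sizes used by the test-suite and acceptance runs

Property suites run on 30--96 pixel grids (100 random scenes for the
sampling constraints); recovery runs use 256 × 256 two-year scenes with six
injected 1 ha events over five seeds, and the acceptance script one such
scene. These sizes keep per-class sample counts and component statistics in
a regime where the assertions are meaningful while a full run stays
comfortably within a desktop R session.

## Known limitations

* Spectral signatures are stand-ins, not calibrated to any specific region;
  per-class statistics for the original study areas are not published.
* The raster file format is float TIFF plus a JSON sidecar for the affine
  transform and band names — readable anywhere, but not a georeferenced
  GeoTIFF with embedded tags, and no reprojection is offered.
* Sub-annual change timing, distinguishing clear cuts from degradation
  within the woody-to-non-woody class, and area-adjusted (Olofsson-style)
  estimators are out of scope.
* Whether the operational 3σ rule used one- or two-sided exceedance and
  union or intersection of the two indices is not documented; both are
  exposed as options with the defaults argued above.
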