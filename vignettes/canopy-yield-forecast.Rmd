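---
title: "Forecasting olive on-year yield from canopy geometry and orthoimagery"
author: "CanopyYield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting olive on-year yield from canopy geometry and orthoimagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CanopyYield)
```

## The problem

Olive production alternates between high-bearing ("on") and low-bearing
("off") years. In an on-year, the per-tree actual yield AY (kg/tree) is
strongly determined by canopy size, so a forecast of AY — and of the
orchard-level yield OAY = mean(AY) x planting density (kg/ha) — can be
built from tree geometry alone. Two geometric predictors are used:

* **Manual canopy volume (MCV, m3)**: an ellipsoid approximation measured
  with a surveying rod,
  \[
  MCV = \frac{\pi}{6} D_1 D_2 \cdot
        \frac{(Ht_1 - Hs_1) + (Ht_2 - Hs_2)}{2},
  \]
  where \(D_1, D_2\) are the crown diameters in two perpendicular passes,
  \(Ht\) the tree height and \(Hs\) the skirt height (lowest canopy above
  ground). `manualCanopyVolume()` implements this, validating
  \(D \ge 0\) and \(0 \le Hs \le Ht\).
* **Individual crown area (ICA, m2)**: the vertically projected crown
  area, extracted from an RGB orthoimage acquired by a small UAS. ICA
  replaces MCV where rod measurements are impractical, because within an
  orchard tree heights are nearly uniform, making projected area an
  effective proxy for volume.

The forecast models are simple linear regressions, fitted for southern
Spain orchards (traditional, intensive and large-hedgerow categories;
super-high-density orchards with non-ellipsoidal hedge profiles are out of
scope):

| model | equation | r2 | SE |
|---|---|---|---|
| general | AY = 15.928 + 1.215 MCV | 0.76 | 18.6 kg/tree |
| irrigated | AY = 10.642 + 1.541 MCV | 0.89 | 13.1 kg/tree |
| rainfed | AY = 25.932 + 0.781 MCV | 0.62 | 17.1 kg/tree |
| area-to-volume | MCV = -7.906 + 3.080 ICA | 0.83 | 16.77 m3/tree |

`publishedModels()` carries these as immutable `LinearModel` objects. The
r2 and standard errors are reported metadata: they summarise the original
field data, which is not distributed, so this package can verify the
coefficients exactly but cannot refit the diagnostics. What it *can*
verify — and does, in the test suite — is the statistical machinery: on
synthetic populations with a known generating line and residual spread,
`fitOLS()` recovers slope and intercept with 95% confidence intervals that
cover the truth at nominal rate.

The chained forecast `forecastAYfromICA()` composes the area-to-volume
model with a regime yield model. Both slopes are positive, so forecast
yield is strictly increasing in crown area. Predictions are never clamped:
a crown below 2.567 m2 yields a negative volume estimate, which is kept
and flagged with a warning rather than silently altered — the published
models are linear and the package reproduces them as such.

## Crown delineation from orthoimagery

`runPipeline()` reproduces the image-analysis chain of the original
ImageJ-based procedure:

1. **Scale calibration** — `calibrateScale(px, m)` converts a known ground
   reference to a pixel size (m/pixel). Orthoimages read from PNG carry
   this in a sidecar JSON. GeoTIFF geotransforms are not parsed; TIFF
   rasters are supported with an explicit pixel size.
2. **Working channel** — the green band by default (the channel named for
   segmentation), with the HSL lightness grayscale
   \((\max(R,G,B)+\min(R,G,B))/2\) available via
   `extractChannel(img, "lightness")`.
3. **Dual thresholding** — one threshold removes bright soil, a second
   removes dark shadow. The band convention is fixed: a pixel is canopy
   iff `shadow < v <= ground`. The original thresholds were chosen
   manually; `suggestThresholds()` automates the choice with Otsu's
   criterion (exhaustive between-class-variance search on the 0–255
   histogram), applying it once for the soil cut and again on the
   sub-histogram at or below it for the shadow cut.
4. **Particle analysis** — `labelRegions()` labels connected canopy
   components (run-length encoding + union-find; 8-connectivity by
   default, matching common particle-analysis behaviour, 4 available),
   assigns labels in raster-scan order, computes pixel counts, areas
   (`pixelCount x pixelSize^2`), world centroids, bounding boxes and
   pixel-edge outline polygons (closed, counter-clockwise; for hole-free
   regions the ring encloses exactly the component's pixels).

Numerical conventions, fixed and tested: image indices are 1-based
row-major in R; world coordinates put the top-left pixel corner at the
image origin with x east and y north; centroids are means of pixel
centres. Touching crowns are *not* split — no watershed is applied,
mirroring the original procedure — but regions larger than `maxArea`
trigger a merged-crown warning. The default `minArea` of 1 m2 suppresses
weed and noise speckle; it is a package default, not a reported setting
(the original particle-size filter is unreported).

## The synthetic orchard generator

No field data are deposited, so the generator provides populations with
the reported statistical structure, making every downstream stage testable:

* **Layouts**: rectangular grid (or quincunx offset rows) at the reported
  spacings (6 x 3 m to 12 x 12 m) with a half-spacing margin. The tree
  count is the floor-convention density (`floor(10000/(a b))`, which
  matches 8 of the 9 computable printed densities; 12 x 12 m is quoted as
  70 but floors to 69) scaled to the field area and capped by grid
  capacity — a 1-ha 12 x 12 m grid physically holds 8 x 8 = 64 trees.
* **Populations** (defaults from the reported on-year means and SDs):
  MCV ~ truncated normal (> 1 m3) with 12.1 ± 1.7 m3 (irrigated
  intensive), 73.6 ± 27.6 m3 (rainfed traditional) or 98.0 ± 9.9 m3
  (irrigated traditional); canopy height ~ truncated normal (> 0.5 m)
  with 3.8 ± 0.2 m (irrigated) or 3.9 ± 0.4 m (rainfed). The reported
  heights are tree heights; the generator uses them directly as the
  ellipsoid's vertical axis (skirt folded to zero), since per-tree skirt
  heights are not reported. MCV and height are drawn independently — no
  joint distribution is reported. Truncation bounds are package choices
  to keep records physical.
* **Geometry**: crowns are circular by default (`d1 = d2`, an optional
  eccentricity ratio splits them) with `d1 d2 = 6 MCV / (pi h)` so the
  ellipsoid model reproduces the latent MCV exactly, and
  `ICA = pi d1 d2 / 4`. The generator deliberately links ICA to MCV
  *geometrically*, not through the published area-to-volume regression:
  that regression's slope then becomes a recoverable quantity (for
  constant height h the implied slope is h/1.5) instead of an input,
  which avoids validating the chained forecast against its own
  definition.
* **Yield**: AY = regime line(MCV) + Gaussian(0, residual SD), truncated
  at zero, with residual SDs 13.1 (irrigated) / 17.1 (rainfed) kg/tree —
  the reported standard errors of the regime fits.
* **Rendering**: `renderOrthoimage()` draws soil (RGB 196/172/120), crown
  ellipses (70/96/52) and shadow ellipses offset by a sun vector
  (38/38/38), adds Gaussian pixel noise (SD 6) and quantises to 8 bits at
  0.02 m/pixel by default. Green-band modes (soil 172, crown 96, shadow
  38) are separated by many noise SDs, so dual-threshold segmentation is
  exact up to rasterisation: recovered areas match the analytic ellipse
  area to well under the one-perimeter-pixel discretisation band.

What the renderer does **not** emulate: texture, within-crown radiometric
variation, weeds and intercrop vegetation, uneven illumination,
orthomosaicking artefacts, or crowns whose projection is non-elliptical.
Passing the end-to-end recovery tests therefore demonstrates the
correctness of the scale/segment/label/measure chain, not segmentation
robustness on real imagery — on real orthoimages the thresholds remain a
manual, image-specific choice, as in the original procedure.

A single RNG stream is seeded once per run (`OrchardSpec@seed` or the
pipeline config seed), making every output reproducible; generation with a
given seed is deterministic, as the pipeline tests assert byte-identical
CSV outputs.

## Orchard aggregates and thematic mapping

`orchardAggregates()` computes OAY = mean(AY) x density,
orchard canopy volume = mean(MCV) x density (m3/ha), and production per
canopy volume as the *mean of per-tree AY/MCV ratios* (the printed
"kg/m3 ± SD" values imply a per-tree distribution, so the mean-of-ratios
is used rather than the ratio of means); zero-volume trees are excluded
from the ratio with a warning. Units are fixed throughout: metres,
kilograms, hectares — no unit inference.

`buildYieldMap()` attaches the chained forecast to each delineated crown
and bins forecasts into discrete classes — five quantile classes by
default (the original map's class scheme is unprinted; fixed edges are
available). The orchard estimate is the summed per-tree forecast divided
by the image footprint in hectares (the full extent, not the tree hull).
`exportYieldMap()` writes GeoJSON (crown outline polygons with `ica_m2`,
`mcv_m3`, `ay_kg`, `class`), CSV, and a rendered PNG with a discrete
colour ramp and legend.

## Design decisions that were genuinely open

* **Density rounding**: the printed densities are internally inconsistent
  (7 x 9 m implies floor; 12 x 12 m implies rounding up). Flooring
  matches 8 of 9 rows and is used everywhere; the 12 x 12 m discrepancy
  is asserted, not hidden.
* **Fitting data**: whether the general yield model was fitted on pooled
  per-tree data or orchard means is unstated; `fitOLS()` takes per-tree
  data and the parameter-recovery tests assume that.
* **Threshold channel**: both a lightness grayscale and the green band
  are named in the source procedure; the green band (the one named for
  segmentation) is the default, lightness a flag.
* **Interval convention**: no threshold convention is stated;
  `shadow < v <= ground` is fixed and tested. Otsu tie-breaks take the
  lowest maximiser.
* **OLS implementation**: coefficients use two-pass mean-centred sums;
  degenerate inputs (constant predictor, n < 3) are rejected rather than
  pseudo-inverted. `stats::lm` serves as an independent oracle in the
  tests, never as the implementation.
* **Problem sizes**: the end-to-end checks run a 1-ha orchard at
  0.02 m/pixel (a 5000 x 5000 raster) and 200 replicates of n = 518 for
  parameter recovery; smaller fixtures (coarser pixels, 50 x 50 m fields)
  are used where a property does not need full scale.

## Limitations

* Thresholding is global; orchards with strong illumination gradients
  would need per-tile thresholds or radiometric normalisation, which the
  original mosaics did not require.
* Merged crowns are reported as single regions; hedgerow orchards with
  touching canopies need a splitting step (e.g. watershed) that is
  intentionally out of scope.
* The published coefficients are specific to southern-Spain conditions
  and on-years; no off-year model exists (off-year data showed no
  significant regression), and multiple regression is deliberately
  omitted (the tool targets single-predictor use).
* Heights from digital surface models are not used; crown area alone is
  the image-side predictor.

## A worked example

```{r example, eval = FALSE}
spec <- orchardSpec(c(12, 12), regime = "irrigated",
                    category = "traditional", seed = 42)
trees <- generateOrchard(spec)         # 64 trees on 1 ha
img <- renderOrthoimage(trees, spec)   # 5000 x 5000 px at 0.02 m/px
thr <- suggestThresholds(extractChannel(img, "green"))
mask <- segmentCanopy(img, segmentationParams(thr$ground, thr$shadow))
crowns <- labelRegions(mask, pixelSize(img), minArea = 1,
                       origin = imageOrigin(img))
map <- buildYieldMap(crowns, "irrigated")
map
exportYieldMap(map, "yield_map.geojson", "geojson")
```
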