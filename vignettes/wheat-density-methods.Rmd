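---
title: "Estimating wheat plant density from RGB imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wheat plant density from RGB imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wheat plant density (plants per square metre) is a management-critical trait
that is still mostly obtained by visually counting seedlings along row
segments shortly after emergence, around Haun stage 1.5 when plants carry
one to two erect leaves. `wheatdens` automates that survey from
high-resolution RGB images taken obliquely (about 45°) across the rows. The
central difficulty is that neighbouring seedlings touch: a connected patch
of green pixels ("object") may hold zero, one, or several plants, so objects
cannot simply be counted. The pipeline instead *estimates the expected
number of plants in each object* from its morphology and sums those
continuous estimates over the imaged row segments.

The stages are:

1. **Segmentation.** The image is converted to CIELab and the a*
   (green-magenta) channel is thresholded by Otsu's criterion. Chlorophyll
   pushes a* strongly negative while soil browns sit at positive a*, so the
   low-a* class is always vegetation. The conversion assumes the sRGB
   working space with D65 reference white and piecewise gamma decoding; the
   Otsu histogram uses 256 bins linearly stretched over the observed a*
   range, values exactly at the threshold going to background, and a
   constant a* channel raises a typed degenerate-input condition rather
   than guessing.
2. **Rectification.** A chessboard image taken per camera setup calibrates
   a projective map from image pixels to the ground plane (normalized DLT
   on the detected interior corners). Remapping onto a regular metric grid
   (default 0.6 mm/px here; configurable) removes the perspective scale
   gradient so that areas and row spacings become comparable across the
   image. Lens distortion is not modelled.
3. **Row detection.** Rows are found with an edge-point Hough transform,
   ρ = x·cosθ + y·sinθ (θ = 90° meaning horizontal rows), with the
   classical axes of 0.1° and 1 px. Orientation and row offsets are
   recovered as described below, the mask is rotated by 90° − θ_row so rows
   are horizontal, and every object is assigned to its nearest row line.
4. **Features.** Each 8-connected component is described by 13 features:
   pixel area, filled area, convex-hull area, solidity, extent, equivalent
   diameter, the moment-ellipse major/minor axis lengths, eccentricity and
   orientation (regionprops conventions, including the +1/12 per-pixel
   variance term), plus skeleton length, end-point count and branch-point
   count from a Zhang-Suen thinning of the object.
5. **Counting.** A one-hidden-layer network with `k_n` tangent-sigmoid
   hidden nodes and a linear output maps z-scored features to a continuous
   expected plant count (clipped at zero, never rounded). `k_n = 2` is the
   default. Weight-based recursive feature elimination prunes the 13
   features to the smallest subset whose held-out RMSE stays within 1.02 of
   the best observed along the elimination path.
6. **Density.** Continuous counts of the objects lying on the counted rows
   are summed and divided by the segment area (segment length × row spacing
   × number of rows).

## Row orientation: criterion and refinement

The classical criterion - pick the θ whose accumulator column has the
largest variance of vote counts over ρ - is implemented verbatim in
`row_orientation()` and works as intended when rows are thin strings of
points. On realistic seedling imagery, however, each erect leaf projects as
a short stroke oriented *across* the rows; these strokes concentrate votes
at the perpendicular orientation and can dominate the raw variance
criterion. `detect_rows()` therefore scores each orientation by the
variance of the *band-smoothed* profile (boxcar of a quarter row spacing)
multiplied by the profile's autocorrelation contrast at the sown row
spacing: correlation at one spacing minus correlation at half a spacing.
Genuine rows alternate at the sown period, so they score high; leaf-scale
clutter and broad non-row structure are correlated at both lags and are
suppressed. The sown spacing is known from the drilling configuration and
is already a required input of the density stage, so this adds no new
information requirement.

A Hough bin is 0.1°, but the band criterion alone cannot localize the peak
to one bin: a row is a band of scattered plants, not a line. The orientation
is therefore polished by a small number of fixed-point iterations that
rotate object centroids into the candidate frame, locate row centres on the
smoothed across-row histogram, and fit one common slope through all rows
(weighted by object area, since merged objects average more plants and have
tighter centroids). The statistical floor of this estimator is set by the
centroid scatter of individual plants (≈ 25 mm) over the segment length:
about 1° for a 0.45 m segment with ~100 plants, and about 0.05° for a 2.5 m
segment at 600 seeds·m⁻². Orientation-accuracy validation therefore uses
2.5 m segments - commensurate with the ≥ 10 m field plots the survey
protocol assumes - while the fast desk-scale scenes accept a degree-level
orientation error, which the density stage tolerates easily.

Row offsets come from peaks of the rotated edge-vote profile at θ = 90°:
local maxima above 0.3 of the tallest peak, accepted greedily with a
minimum separation of 0.6 × the sown spacing, each refined by a windowed
centroid. A row holding only two or three emerged plants can genuinely fall
below the prominence threshold; the aggregation protects itself against
such misses (below).

## The count model

The network is `count = b2 + w2 · tanh(W1 x + b1)` on z-scored features.
It is fitted by Levenberg-Marquardt least squares (a second-order batch
method) with a small L2 weight penalty (1e-4) for conditioning, run in
chunks of 25 iterations up to 200, with an internal 10% validation split:
the weights kept are those with the best validation RMSE and fitting stops
once validation stalls. Several random restarts (3 by default) guard
against poor local minima; everything is deterministic given the seed.
Null objects (count 0: stones, residue, severed plant fragments) stay in
the training set - the network must learn to assign them near-zero counts.

Feature importance is the classical weight product
`importance(j) = Σ_h |W1[h, j]| · |w2[h]|`. Recursive elimination retrains
after every drop (true recursion, not rank-once), measuring each subset
size with the *same* five 90/10 splits - a paired design, so the
1.02 × RMSE_best selection rule compares subset sizes on identical held-out
draws instead of being confounded by split-to-split noise. RMSE_best is the
minimum mean RMSE observed anywhere along the elimination path. The
architecture search (`select_architecture()`) uses the same splits for all
candidate `k_n` and retains the smallest network within the same 2%
tolerance of the best, with an absolute floor of 0.01 plants so that
perfectly learnable targets select the single-node network.

## Density aggregation

Density is the sum of continuous counts divided by segment length × row
spacing × number of counted rows. Objects are counted when their centroid
assigns to a counted row *and* lies within half a sown spacing of that row
line. This guard makes the estimate robust to a missed row: the plants of
an undetected (typically nearly empty) row are excluded together with that
row's share of the area, leaving the ratio consistent. A
two-central-rows mode (`rows_counted = 2`) mirrors the visual reference
protocol. With ground-truth counts substituted for predictions
("oracle" mode), the estimate reproduces the generator's density exactly,
which isolates the geometric stages from the learning stage in validation.

## The synthetic scene generator

No field imagery ships with the package, so every claim is validated
against `generate_scene()`, which renders ground-truthed scenes that
emulate the statistical structure of early-stage wheat imagery:

- Plants are placed along each row by a homogeneous Poisson process at
  sowing density × emergence rate (default 0.9), with 2.5 mm across-row
  jitter; overlap and multi-plant objects emerge naturally as density
  grows, producing the characteristic right-skewed plants-per-object
  distribution with mode one.
- A plant carries 1-2 leaves rendered as tapered, randomly bent strokes
  (length 20-60 mm, width 1.5-3 mm, oriented mostly across-row as erect
  leaves appear under a 45° view), joined at a small basal blob so each
  plant is one connected region.
- Soil is a brown base with smoothed and per-pixel Gaussian noise plus
  occasional bright stones that stay on the soil side of the a* threshold.
- Distractors - dull-green elliptical blobs standing in for residue and
  stones with plant-like colour - are injected at a rate calibrated so
  that roughly 10-20% of segmented objects contain no plant, matching the
  null-object fraction reported for field data.
- The ground truth records every plant's pixel footprint, the per-object
  plant counts under 8-connectivity, the true row lines in Hough
  parameters, and the exact density of the rendered segment. An optional
  known homography produces an oblique camera view for exercising the
  calibration path end to end.

Default desk-scale geometry is five rows at 175 mm spacing, 0.45 m
segments, rendered at 0.6 mm/px. What passing tests show is that the
pipeline recovers its own generator's truth under these statistics; the
generator does not model illumination changes, specular soil, wind-blurred
leaves, weeds, or cultivar-specific leaf shape, so field performance must
still be established per site - as the per-site training protocol already
assumes.

## Validation scales and expectations

The bundled validation (also re-run by `scripts/acceptance.R`) uses:

- End-to-end: 50 training and 30 test scenes spanning 100-600 seeds·m⁻²;
  the mean relative density error is required to stay at or below 12%.
- Per-object: 40 scenes at 100-300 seeds·m⁻²; the held-out RMSE of the
  retained feature subset is required to stay at or below 0.68 plants per
  object.
- Geometry: oracle-count identity on 0.9 m scenes across the density
  range; orientation recovery within 0.1° on 2.5 m scenes over angles from
  -89° to +89°; chessboard calibration reprojecting within 0.5 px.

Per-object error grows with density (overlapping plants make large
ambiguous objects), so the density error is expected to degrade towards
600 seeds·m⁻²; the end-to-end check asserts that ordering as well.

## Known limitations

- The row detector needs the periodic multi-row structure: scenes with a
  single row, or rows holding only a handful of plants over a short
  segment, sit outside its envelope (typically ≥ 3 rows and ≥ 15 plants
  per row are needed for reliable counts, degree-level orientation needs
  ≥ ~100 plants).
- Skeleton pixel sets depend on the thinning variant; only topology
  (components, holes, end/branch points) and counts are contracted, not
  pixel identity. Branch points are counted as junction clusters, since
  pixels flanking a junction are mutual diagonal neighbours and would
  otherwise inflate the count.
- Object orientation (F10) flips sign under vertical reflection and is
  near-meaningless for round objects; it carries little information for
  counting, consistent with its elimination by RFE.
- All validation is synthetic; the package has not been exercised on field
  imagery.
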