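---
title: "Foveal specialization morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foveal specialization morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveamorph)
```

The human fovea concentrates several anatomical specializations in a fraction
of a square millimetre: cone photoreceptor density peaks, the inner retinal
layers are displaced to form a pit, the outer nuclear layer (ONL) thickens,
and the capillary network leaves a foveal avascular zone (FAZ). `foveamorph`
quantifies each of these from its standard imaging-derived input — cone
coordinates from adaptive-optics scanning light ophthalmoscopy (AOSLO),
boundary segmentations from directional OCT (D-OCT), ILM–RPE thickness maps
from OCT volumes, and binarized vessel masks from OCT angiography — and
relates them across a cohort with rank-based statistics. Every stage has a
matching synthetic-data generator with known ground truth, so the whole
pipeline is validated by parameter recovery rather than against
irreproducible study data.

## Geometry and calibration

All lateral dimensions are corrected for ocular axial length: OCT devices
convert scan angle to millimetres assuming a fixed eye length (24.46 mm for
the Cirrus HD-OCT), so the true extent of a scan is the nominal extent times
(measured axial length / 24.46). `correct_lateral_scale()` applies this ratio
and rejects axial lengths outside a configurable 18–32 mm plausibility window
(catching unit errors, not unusual eyes). Images use a 0-based, pixel-center
convention: the top-left pixel center is the physical origin, x increases
along columns, y (or depth z for B-scans) along rows. The axial (depth) pixel
scale is treated as a device constant; no axial-length correction is applied
to it.

## Cone density metrics

`density_map()` slides a square counting window (default side 50 µm) over the
cone coordinates on a regular grid of window centers (default step 1 µm).
Window membership uses half-open intervals so each cone belongs to a
well-defined set of windows, and only windows fully inside the region of
interest are evaluated — partial windows at the edge would otherwise inflate
variance. The window must be much larger than the cone spacing (~2–3 µm at
the foveal peak) for stable counts and much smaller than the 300 µm ROI to
retain topography; 50 µm satisfies both with room to spare, and both
parameters are configurable. When the window side is a multiple of the grid
step the counts come from a summed-area table and are exactly equal to a
per-window recount (this equivalence is asserted in the tests against a
brute-force oracle).

Peak cone density (PCD) is the map maximum; plateaus of tied integer counts
are resolved deterministically (node nearest the ROI center, then row-major).
The cone density centroid (CDC) summarizes the high-density region instead of
a single noisy pixel: the map is thresholded at a fraction of PCD (default
0.8), the 8-connected supra-threshold component containing the PCD node is
kept, and its density-weighted centroid is the CDC. The phrase "80%
isodensity contour of the top 20th percentile densities" admits two readings
— a contour at 0.8 × PCD, or a contour derived from the top 20% of map values
— and this package implements the former with the fraction exposed as a
parameter; it does not attempt to guess further. The unweighted centroid is
available (`weighted = FALSE`).

Areal foveal cone density aligns all maps at their CDC, finds the largest
half-width `h` such that every map covers `[CDC − h, CDC + h]` on both axes,
and averages each map's bilinearly interpolated density along the horizontal
row through its CDC over that span. Whether a published "common area" of this
kind refers to a half-width or a full width is ambiguous, so both `h` and
`2h` are reported; outputs use the full width `2h`. For the central ONL
thickness below, the same convention (full width 0.227 mm, i.e. ±113.5 µm) is
used.

## ONL thickness from directional OCT

On conventional OCT the Henle fiber layer (HFL) blends into the ONL, inflating
its apparent thickness. Directional OCT resolves the HFL/ONL boundary by
acquiring the same line scan through different pupil entry positions.
`align_doct()` registers the off-axis scans to the central one by the integer
translation maximizing cross-correlation (computed via FFT), reporting the
normalized cross-correlation at the optimum; scores below 0.5 are flagged,
mirroring the manual rejection of poorly aligned triads. Rotation and scaling
are deliberately out of scope — alignment quality was historically judged by
eye on RPE/ILM/choroid contours, and translation suffices for co-registered
line scans. `merge_doct()` is a pixelwise maximum projection (idempotent,
commutative, monotone — all asserted as properties).

Five boundaries (ILM, OPL/HFL, HFL/ONL, ELM, RPE; nominally 30 manual points
each) are linearly interpolated; queries outside the knot span are an error
rather than an extrapolation, because the manual points bound the trusted
region. ONL thickness is `z(ELM) − z(HFL/ONL)` scaled by the axial sampling.
The foveal center is not defined by the source methodology, so this package
defines it operationally as the minimum of total retinal (ILM–RPE) thickness
on a 1 µm grid within ±750 µm of the scan middle, with ties resolved to the
midpoint of the tying interval. The maximum "foveal" ONL is searched within
±500 µm of that center (a window is needed to exclude parafoveal artifacts;
the value is configurable), and the central ONL is the trapezoidal mean over
±113.5 µm. The evaluation step (5 µm) is far below the ~200 µm knot spacing,
so discretization is negligible against the interpolation error itself.

Because the profile between knots is piecewise linear, its deviation from a
smooth truth is bounded by `(knot spacing)² · max|f''| / 8`; the test suite
generates analytic profiles and asserts the observed error stays below this
bound. A consequence worth knowing: the thickness minimum of a piecewise
linear profile always falls on a knot, so foveal-center localization is
knot-limited. The synthetic generator therefore anchors one knot at the scan
center (as a grader marking the foveal center would), and center-offset
scenarios should use offsets that are multiples of the knot spacing if exact
recovery is expected.

When two graders segment the same scans, `grader_average()` combines them and
`icc_two_grader()` quantifies agreement (below).

## Foveal pit morphometry

The pit is measured from the ILM–RPE thickness map by an explicit radial
rim-detection procedure (the published algorithms this emulates are described
only at the level of "rim-based diameter and volume", so the operational
definition here is the package's own and all thresholds are exposed):

1. **Center**: minimum thickness within 750 µm of the map's geometric
   center, after light box smoothing (default half-width 50 µm per axis) —
   the pit bottom is locally flat, so a raw single-pixel minimum wanders by
   ~100 µm under a few micrometres of measurement noise — refined by a
   separable quadratic fit.
2. **Radial profiles**: 180 rays, 10 µm radial step, up to 3 mm, bilinearly
   interpolated in physical micrometres so the strongly anisotropic grid
   (nominally 512 × 128 over 6 × 6 mm) is handled transparently.
3. **Rim**: on each smoothed ray (moving average, half-width 2 samples), the
   first local maximum moving outward whose topographic prominence reaches
   2 µm; if no ray maximum is prominent the global maximum is used and
   flagged. Radius and height are refined by a quadratic fit whose vertex is
   clamped to the range of its three samples (an unclamped parabola
   overshoots at plateau edges).
4. **Diameter**: mean over opposed ray pairs of `r(θ) + r(θ + π)`, in mm,
   with missing pairs excluded and counted.
5. **Volume**: the sum over map pixels inside the rim of
   `max(0, rim_height(θ) − thickness)` times pixel area, with the rim radius
   and height interpolated periodically in angle. Using the per-angle rim
   height (rather than one plane) tolerates tilted maps, and the clipping at
   zero makes the volume non-negative by construction.

Rotation invariance, scale equivariance (diameter ∝ s, volume ∝ s²) and
monotonicity under pit deepening are asserted as property tests.

## FAZ morphometry

Repeated angiograms are averaged (`average_angiograms()`), binarized
(`binarize_vessels()`, Otsu by default with a fixed-threshold fallback;
already-binary images pass through), and the avascular regions are labelled.
Parafoveal intercapillary areas (PICAs) are the 4-connected components of
non-vessel pixels — 4-connectivity prevents diagonal leakage through
8-connected capillary walls. Regions touching the image border are flagged
and never FAZ candidates: they are unbounded intercapillary space, not
enclosed PICAs. The largest PICA whose centroid lies within the central
region (default radius 500 µm around the image center — generous relative to
normal FAZ extents, and configurable, since the source tooling does not
publish its definition) is assigned as the FAZ. Each central PICA's area
ratio to the largest is computed; the FAZ is classified as fragmented when
two or more ratios strictly exceed 0.3, and the FAZ area is the largest
central area regardless of fragmentation. Centroid-based centrality was
chosen over any-pixel overlap because it is deterministic and insensitive to
finger-like protrusions.

## Statistics layer

Associations use Spearman rank correlation (Pearson correlation of mid-ranks;
p from the t approximation on n − 2 df; 95% CI by Fisher z with the
rank-correlation standard error 1.03/√(n − 3)). Intergrader agreement uses
ICC(2,1) — two-way random effects, absolute agreement, single rater — so that
a systematic offset between graders, which a paired t test can detect,
correctly penalizes agreement; a consistency variant is selectable since the
model behind published "intraclass correlation coefficients" is often
unstated. The CI is the standard F-based interval. Cohort summaries report
min/max/median and IQR with linear-interpolation quantiles. No
multiple-testing correction is applied by default (matching common practice
of reporting raw p for descriptive correlation sets); Holm adjustment is
available.

## Synthetic data: what it emulates, and what it does not

Each generator returns its ground truth alongside the data, and the test
suite closes the loop generate → measure → compare.

- **Cone mosaics** (`synth_mosaic()`): variable-radius dart throwing places
  cones with local spacing tied to a Gaussian density profile (defaults: peak
  2 × 10⁵, base 5 × 10⁴ cones/mm², σ 100 µm — spanning the densities reported
  for healthy adult foveae). Random sequential packing saturates below the
  density its spacing implies; the proposal density is inflated by a
  packing-calibration factor (1.111, measured once on uniform fields) so the
  realized density tracks the request, and the generator verifies itself to
  within 10% at the peak. Dart throwing reproduces the irregular-but-inhibited
  character of a real mosaic; it does not model reflectance variation,
  detection misses, or rods.
- **Boundary segmentations** (`synth_segmentation()`): an analytic layered
  model (Gaussian ONL bump, defaults 60 + 40·exp(−x²/(2·600²)) µm; Gaussian
  pit in total thickness, σ 400 µm) sampled at 30 knots with optional
  Gaussian depth noise, ordering enforced. The ONL fall-off scale and the
  center-anchored knots are chosen so the stated recovery tolerances are
  attainable given the piecewise-linear error bound; a sharper pit keeps the
  knot-limited center localization noise-robust. No speckle, no curvature,
  no segmentation blunders.
- **Thickness maps** (`synth_thickness_map()`): radially symmetric surface
  `t_rim − (t_rim − t_center)·exp(−(r/r₀)²) − slope·max(0, r − onset)²`. The
  outer fall-off must begin inside the rim (default onset 0.7 × rim radius):
  if it began at the rim itself the Gaussian term's positive slope there
  would always push the true maximum outward, and no r₀ could place the rim
  exactly. With the inset onset, r₀ is solved numerically so the densely
  located profile maximum sits at the requested rim radius, and the reference
  volume comes from fine polar quadrature.
- **Vessel masks** (`synth_vessel_mask()`): Voronoi-cell walls of Poisson
  seeds around a circular FAZ whose boundary loop grows outward, so the
  enclosed open area is the exact pixel-counted disk; an optional traversing
  capillary splits the FAZ at a column chosen to match requested proportions,
  with true fragment areas returned. Real capillary networks are not Voronoi
  diagrams; the generator provides controlled enclosed areas, not realistic
  perfusion.
- **Cohorts** (`synth_cohort()`): Gaussian copula with target Spearman matrix
  (converted via ρ_P = 2·sin(πρ_S/6), nearest-PSD-repaired if needed) and
  scaled-Beta margins calibrated to each metric's published minimum / median /
  maximum — bounded and skewed, unlike Gaussian margins. The default target
  matrix uses reported cross-modality correlations where available and
  plausible values for unreported within-modality pairs; these are scenario
  parameters, not estimates.

Passing recovery tests on these generators demonstrates that the estimators
are consistent with their own definitions under controlled conditions; it
does not certify behaviour on real images with motion artifacts, segmentation
errors, or pathology.

## Numerical choices and degenerate inputs

Bilinear interpolation is used everywhere a gridded quantity is read off at
physical coordinates; queries outside the grid are `NA` (profiles) or errors
(no extrapolation of boundaries). Quadratic refinements clamp both the offset
(±0.5 sample) and the value (sample range). Degenerate cases have defined
behaviour: a flat thickness map returns the geometric center with a warning;
a single-node isodensity contour warns; zero-variance paired differences give
t = 0 (all-zero) or a flagged p = 0 (constant nonzero); constant inputs to
Spearman or Otsu are errors. Problem sizes in the test suite (10–20 mosaics
at full 300 × 300 µm ROI and 1 µm grid step, 100 noisy segmentations, 500
statistical replicates at n = 68) were chosen to exercise the estimators at
the cohort's realistic scales while keeping a full run in a few minutes.

## Known limitations

- The pit diameter/volume procedure is an operational equivalent of
  rim-based definitions, not a reimplementation of any specific published
  code; equivalence with other implementations cannot be asserted, only
  internal consistency.
- Foveal-center localization on B-scans is knot-limited (see above).
- The FAZ central region and the binarization method are package defaults
  where the source tooling leaves them unspecified.
- `run_pipeline()` computes whatever modalities are present per participant
  and marks the rest missing; it does not attempt cross-modality imputation
  or registration between modalities.
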