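# foveamorph

Quantitative morphometry of human foveal specialization from multimodal
retinal imaging, for vision scientists and ophthalmic imaging groups who
already have processed imaging products — cone coordinates, layer
segmentations, thickness maps, vessel masks — and need reproducible metrics
and cohort statistics on top of them.

The fovea concentrates several specializations that are measured with
different devices:

- **Cone density** (AOSLO): a sliding-window density map `D(x, y)` over cone
  center coordinates; **PCD** = max `D`; the **cone density centroid (CDC)**
  = density-weighted centroid of the 8-connected component of
  `{D ≥ 0.8 · PCD}` containing the peak; **areal foveal density** = mean of
  `D` along the horizontal row through the CDC over the cohort-common span
  after CDC alignment.
- **ONL thickness** (directional OCT): off-axis B-scans aligned by integer
  translation (max cross-correlation) and merged by pixelwise maximum; five
  manually segmented boundaries interpolated piecewise-linearly; true ONL
  thickness = `z(ELM) − z(HFL/ONL)`, summarized as the maximum near the
  foveal center and the mean over the central 0.227 mm.
- **Foveal pit** (OCT thickness map): radial rim detection — pit center at
  the smoothed thickness minimum, per-ray rim at the first prominent local
  maximum, diameter = mean rim-to-rim extent, volume = ∑ max(0, rim height −
  thickness) · pixel area inside the rim.
- **FAZ** (OCTA): parafoveal intercapillary areas (PICAs) = 4-connected
  avascular components; the largest central PICA is the FAZ; the FAZ is
  *fragmented* when ≥ 2 central PICA/largest-PICA area ratios exceed 0.3.
- **Statistics**: Spearman correlations with Fisher-z confidence intervals
  (SE 1.03/√(n−3)), intergrader ICC(2,1) with F-based CI, paired t tests,
  and median/IQR cohort summaries.

All lateral scales are corrected for ocular axial length (nominal length ×
measured axial length / 24.46 mm). A synthetic-data module generates every
input class with known ground truth (dart-thrown cone mosaics, analytic
layer models, parametric pits, Voronoi capillary beds, Gaussian-copula
cohorts), so the full pipeline is validated by parameter recovery — see the
methods vignette (`vignettes/foveal-morphometry.Rmd`) for the models, the
tunable parameters and the design decisions.

## Worked example

```r
library(foveamorph)

# cone mosaic with a known density peak displaced (30, -20) um from center
sm  <- synth_mosaic(peak_density = 2e5, peak_offset_um = c(30, -20), seed = 42)
met <- cdc(density_map(sm$mosaic, window_side_um = 50, grid_step_um = 1))
met
#> <density_metrics> PCD 202400 at (174.0, 123.0) um; CDC (179.4, 130.8) um, density 199183

# directional-OCT segmentation with analytic ONL(x) = 60 + 40 exp(-x^2/(2*600^2))
onl_metrics(synth_segmentation(seed = 1)$seg)
#> <onl_profile> max ONL 100.0 um at 0 um; central (227 um) ONL 99.4 um

# thickness map with rim placed at 950 um
pit_metrics(synth_thickness_map(seed = 1)$map)
#> <pit_metrics> diameter 1.90 mm, volume 0.054 mm^3, depth 108 um (180/180 rays)

# vessel mask with a circular 300-um FAZ (true area pi * 0.3^2 = 0.2827 mm^2)
faz_area(synth_vessel_mask(faz_radius_um = 300, n_px = 300, um_per_px = 10,
                           seed = 7)$vm)$faz_area_mm2
#> [1] 0.2828

# copula cohort at n = 68 with a planted pcd ~ pit-diameter rank correlation of -0.54
ch <- synth_cohort(n = 68, seed = 11)
spearman_cor(ch$table$pcd, ch$table$pit_diameter_mm)
#> Spearman r = -0.490 (95% CI -0.656 to -0.278), p = 2.267e-05, n = 68
```

The recovered PCD (202 400 cones/mm², +1.2% of the 200 000 truth), CDC
(within 1 um of the true peak at (180, 130)), maximum ONL (exact at the
center knot), pit diameter (1.90 mm for a 950 um rim) and FAZ area (0.2828
vs 0.2827 mm²) illustrate the parameter-recovery loop the test suite runs at
many more operating points.

Real data enter through `read_cone_coords()`, `read_segmentation()`,
`read_thickness_map()` and `read_vessel_mask()` (CSV / TIFF / PNG with JSON
sidecars for scales), and `run_pipeline()` executes every stage over a cohort
manifest, writing `cohort.csv`, `summary.csv`, `correlations.csv` and a
parameter-echoing `run_log.json`.

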