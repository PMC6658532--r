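# junctionPALM

Single-molecule localization and tracking analysis of ER-plasma membrane
junctions, for PALM/sptPALM studies of store-operated calcium entry. After
calcium-store depletion, the ER calcium sensor STIM1 clusters at ER-PM
junctions and gates plasma-membrane ORAI1 channels there; septin filaments
organize the surrounding membrane. junctionPALM provides the quantitative
pipeline such experiments need, starting from localization tables (one
detected emitter per frame, as exported by common SMLM software):

* **I/O and geometry** — delimited localization/track tables with a
  configurable column dialect, fiducial-based drift correction, rigid
  channel registration, ROIs in nanometre coordinates.
* **Rendering and masks** — averaged-shifted-histogram rendering to 10-nm
  rasters, density filtering (≥ 5 neighbours within 100 nm), Euclidean-disc
  dilation, binary territory and junction masks.
* **Colocalization** — normalized colocalization in green,
  `NCG = (coloc/green)/(red/total)` (1 = random, > 1 enrichment,
  < 1 exclusion), and the stepwise 3-pixel-dilation median distance between
  channels.
* **Tracking** — frame-to-frame linking by exact minimum-cost assignment
  (480-nm displacement cap, no gap closing, ≥ 3-frame lifetime).
* **Diffusion** — MSD curves; the single-step estimator
  `D1 = 1.5 (MSD1 − MSD1,fixed) / (4 · 0.05 s)` with fixed-cell
  localization-error calibration and the 1.5 motion-blur factor; the
  correction-free slope estimator `D2 = (MSD2 − MSD1) / (4 · 0.05 s)`;
  confinement radii `r_c = sqrt(plateau − MSD1,fixed)`; step histograms.
* **Junction analysis** — on/off-junction track classification, maximum
  excursions (d_max over 6–25-step tracks), on-junction single-step D, and
  the two-state engagement fraction
  `(D_LSLD − D_WT)/(D_LSLD − D_STIM1)`.
* **Clustering** — Monte-Carlo-thresholded Voronoi tessellation
  segmentation with watershed (ROI-clipped polygons, CSR null with 100
  iterations, 10-pixel minimum), an 8-connected particle-analysis
  cross-check, and field summaries (clusters/µm², fractional area,
  medians).
* **Synthetic data** — seeded generators with ground truth: two-state
  free/bound diffusion with sub-frame motion blur and localization error,
  stationary calibration emitters, randomized cluster fields, and
  dual-channel enrichment fields.

## Worked example

The fixed-cell calibration and the on-junction diffusion/engagement
arithmetic, end to end:

```r
library(junctionPALM)

cal <- calibrateLocalization(0.0085)   # fixed-cell MSD1 in um^2
cal
#> LocalizationCalibration: MSD1,fixed = 0.0085 um^2 (sigma 2D = 65 nm, per axis = 46 nm)

# wildtype ORAI1 on-junction, siControl/TG: mean first-step r^2 = 0.0147 um^2
dWt <- estimateD1(0.0147, cal)
dWt
#> DiffusionEstimate [single_step_D1]: D = 0.0465 um^2/s

# two-state engagement against the ORAI1-LSLD (free) and STIM1 (bound) references
engagedFraction(dWt, DLsld = 0.0840, DStim1 = 0.0394)
#> EngagementResult: fraction engaged = 0.841  (D_WT 0.0465, D_LSLD 0.084, D_STIM1 0.0394 um^2/s)
```

A 0.0465 µm²/s on-junction diffusion coefficient against a 0.0840 µm²/s
free reference and a 0.0394 µm²/s bound reference means ~84% of junctional
ORAI1 diffuses as if STIM1-bound.

A simulated cluster field, segmented:

```r
sim <- simulateClusterField(clusterSimConfig(seed = 1))
sim$table
#> LocalizationTable: 1664 localizations, channels: green
#>   ROI 4.00 x 4.00 um, frame interval 0.05 s

fld <- voronoiField(sim$table)
thr <- mcDensityThreshold(fld, iterations = 100, seed = 2)
cs  <- segmentClusters(fld, thr$threshold)
cs
#> ClusterSet [voronoi_watershed]: 16 clusters
clusterSummary(cs)[c("nClusters", "clustersPerUm2", "fractionalArea")]
#>   nClusters clustersPerUm2 fractionalArea
#> 1        16              1     0.06158125
```

Sixteen of the 17 planted 200-nm clusters are recovered on this seed (two
planted centers fall close enough for their localization clouds to merge),
at 1 cluster/µm². The fractional area (~6.2%) exceeds the planted disc area
(~3.3%) because each cluster's footprint is broadened by the 70-nm
localization uncertainty.

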