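---
title: "Methods: single-molecule localization and tracking analysis of ER-PM junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule localization and tracking analysis of ER-PM junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

junctionPALM analyzes PALM/sptPALM experiments on store-operated calcium
entry: STIM1 clusters mark endoplasmic reticulum-plasma membrane (ER-PM)
junctions after calcium-store depletion, ORAI1 channels are recruited there,
and septin filaments organize the surrounding plasma membrane. The package
turns localization tables (one detected emitter per frame) into the
quantities this field reports: normalized colocalization between channels,
distances to territories, corrected diffusion coefficients, confinement
radii, junction-referenced trajectory statistics, a two-state
STIM-engagement fraction, and Voronoi-segmented cluster statistics. This
vignette records the models, the tunable parameters, and the numerical
choices, in the order data flows through the package.

## Localization tables, rendering, and spatial conventions

All coordinates are continuous nanometres with the origin at the lower-left
corner of the region of interest (ROI) and y increasing upward. Rasters use
square pixels (10 nm by default) with half-open bins `[k*p, (k+1)*p)`: a
point exactly on a boundary belongs to the higher-index pixel. This
convention is applied uniformly — rendering, mask lookups, cluster
assignment — so pixel-level results are exactly reproducible.

`renderASH()` implements averaged-shifted-histogram rendering: the mean of
`shifts^2` two-dimensional histograms whose bin origins are offset on a
sub-pixel lattice (`shifts = 2` reproduces the common rendering convention
for PALM maps; `shifts = 1` is a plain histogram). Shifted histograms are
clipped at the ROI boundary with edge bins absorbing the shifted-out mass,
so the raster total always equals the number of localizations. Rendering
does not weight localizations by their individual uncertainties; that is a
deliberate non-goal.

Drift correction uses fiducial-marker tracks: the per-frame offset is the
mean fiducial displacement from the first frame (the reference), linearly
interpolated across fiducial blink gaps and held constant beyond a
fiducial's span. More than 10% of frames without any fiducial coverage is an
error rather than a silent extrapolation. Channel registration solves the
least-squares rigid transform from matched fiducial pairs — translation-only
by default, with the two-dimensional Kabsch solution when rotation is
requested. The reported transform maps target-channel coordinates into the
reference channel's frame, so the recovered translation is the negative of
an offset injected into the target.

## Colocalization and median distances

`computeNCG()` evaluates normalized colocalization in green,

NCG = (colocalized pixels / green pixels) / (red pixels / total pixels),

on binary maps. The green channel is always the reference/territory channel
(the photoactivatable-GFP construct — septin 4 or STIM1 — in the
experiments this package serves). NCG equals 1 for a random red channel,
exceeds 1 for enrichment, and falls below 1 for exclusion. A channel with no
set pixels leaves the statistic undefined and raises an error instead of
returning 0. Two properties of the statistic are worth keeping in mind when
it is read as an enrichment estimate. First, it counts *pixels*, not
localizations, so it saturates when per-pixel occupancy is high. Second,
its denominator (red pixels / total pixels) includes the enriched territory
itself, so for a territory covering fraction `a` of the ROI a true density
ratio `e` yields NCG = `e / (1 + a(e-1))` even with perfect sampling — a
compression toward 1 that is negligible for small territories but reaches
~9% for `e = 3` at `a = 0.05`. Planted-enrichment recovery is therefore
validated at ~1% territory fraction and a few percent occupancy, where both
distortions are small.

`medianDistanceToTerritory()` dilates the territory stepwise by 3 pixels at
a time (cumulative Euclidean-disc radius `3k` after `k` steps, computed
through the exact Euclidean distance transform) and recomputes the
fractional coverage of target pixels after each step until it reaches 50%.
The total dilation, converted to nanometres, is the reported median
distance — deliberately kept on the 30-nm quantization grid without
interpolation, mirroring the stepwise procedure it reproduces. It therefore
brackets the true (lower-)median of the distance transform from above
within one step, which the tests assert on random fixtures.

Territory masks and junction masks share one density filter: localizations
with fewer than 5 other localizations within 100 nm are discarded, in a
single pass over the unfiltered table (the filter is not iterated, so it is
independent of record order). Junction masks additionally fill gaps with a
5-pixel (50-nm) Euclidean-disc dilation. Structuring elements are exact
lattice discs (`x^2 + y^2 <= r^2`; 81 pixels at r = 5) rather than the
approximate discs some image libraries provide, because the procedures are
specified in Euclidean nanometres.

## Tracking

`linkTracks()` links detections between consecutive frames by exact
minimum-cost bipartite assignment on squared displacement, with candidate
pairs capped at 480 nm (three 160-nm camera pixels per 50-ms frame) and
birth/death costs equal to the cap squared, so a link is made only when it
is cheaper than leaving both detections unmatched. There is no gap closing:
a missed frame terminates the track, and tracks shorter than 3
localizations are discarded. Optimal assignment was chosen over greedy
nearest-neighbour linking because it is the defensible reference when the
original tracker's internals are unknown; at the sparse densities the
package targets (~0.1 molecules/um^2) linking identity accuracy against
simulation ground truth exceeds 99%, and the choice is recorded in the
track-set metadata.

## Diffusion estimation

MSD curves average squared displacements over all (by default overlapping)
index pairs at each lag, across tracks. Overlapping intervals match common
practice but correlate the samples; the per-lag SEM is computed ignoring
that correlation, which understates the true uncertainty — a documented
limitation, with the non-overlapping alternative exposed.

Two corrected estimators convert MSD values to diffusion coefficients for
50-ms frames:

* **D1 (single step):** `D1 = 1.5 * (MSD1 - MSD1,fixed) / (4 * 0.05 s)`.
  The fixed-cell term removes the localization-error contribution
  (`<r_obs^2> = <r_step^2> + 2*sigma_loc^2`), and the factor 1.5 undoes the
  apparent step contraction caused by continuous acquisition: averaging a
  Brownian path over the exposure shortens the apparent single-step MSD to
  2/3 of its instantaneous value. Negative estimates are reported and
  flagged, never clamped, because truncation would bias ensemble averages.
* **D2 (slope):** `D2 = (MSD2 - MSD1) / (4 * 0.05 s)`. Localization error
  and blur contribute equally to both points and cancel in the difference,
  so no correction is applied.

`calibrateLocalization()` derives `sigma_2D = sqrt(MSD1,fixed / 2)` and the
per-axis `sigma_2D / sqrt(2)` from stationary-emitter tracks; the worked
fixed-cell value 0.0085 um^2 gives 65 nm and 46 nm.

Confined motion plateaus at long lags. For positions uniform in a disc of
radius R the expected squared separation of two independent samples is
exactly R^2, so `estimateConfinementRadius()` reports
`r_c = sqrt(plateau - MSD1,fixed)`, with the plateau taken as the mean MSD
over a 400-500 ms lag window (the notion of "plateau" is not otherwise
defined numerically). Motion blur tightens an apparent plateau — the
time-averaged position of a confined molecule is pulled toward the disc
centre — so r_c from blurred data is a slight underestimate; the simulator's
stroboscopic-sampling mode (`blur = FALSE`) isolates the confinement
geometry when validating this estimator.

## Junction-referenced trajectory analysis

Tracks are classified against a STIM1-marked junction mask: **on** if the
first localization falls inside, **off** if every localization falls
outside, and **excluded** otherwise (enters later; satisfying neither
rule). The excluded class is retained and reported rather than silently
dropped, so the partition is exhaustive and the class sizes are auditable.

Maximum excursion `d_max` is the largest displacement from a track's first
localization to any later localization, computed for tracks of 6-25 steps;
samples of 1500 tracks per condition (seeded, without replacement) are the
conventional reporting unit, and medians the headline aggregate.

On-junction diffusion uses one first step per track: the sample-average
first-step r^2 replaces MSD1 in the D1 formula. Outlying steps with
r^2 > 0.1 um^2 can be excluded, but by default the cut applies to plots
only, not to the mean — the estimator's definition states no trimming.

The engagement fraction assumes junctional ORAI1 has exactly two diffusive
states — free (diffusing like the STIM-blind ORAI1-LSLD mutant) or
STIM1-bound (diffusing like STIM1, which is junction-confined after store
depletion):

fraction engaged = (D_LSLD - D_WT) / (D_LSLD - D_STIM1).

Because the mean single-step r^2 of a mixture is linear in the bound
fraction, this estimator is consistent under its own assumptions; the test
suite verifies recovery of planted bound fractions 0.25/0.5/0.84 within
±0.07 from 1500-track simulations. Values outside [0, 1] are flagged, not
clamped, and `D_LSLD <= D_STIM1` is a model violation and an error. The
bound-state reference uses the condition-averaged STIM1 value when
conditions agree within uncertainty.

## Voronoi cluster segmentation

`voronoiField()` tessellates the localizations and clips every polygon to
the ROI rectangle (half-plane clipping against perpendicular bisectors,
visited in distance order with an early-stopping bound), so polygon areas
sum exactly to the ROI area. Exact duplicate coordinates receive a
deterministic, index-keyed jitter below 0.01 nm, recorded in the result.

`mcDensityThreshold()` builds the complete-spatial-randomness (CSR) null:
100 Monte-Carlo fields matched in localization count and ROI, each
tessellated identically. Observed and mean-CSR polygon-area histograms are
compared on a 50-bin log-spaced grid. The threshold is the area at which
the observed excess of small polygons returns to the CSR expectation,
located as the maximum of the cumulative observed-minus-CSR excess — an
implementation of the histogram-intersection convention that is robust both
to sparsely populated low-area bins and to the compensating excess of
*large* polygons that clustering induces in the diluted background.
Detection is accepted only when that maximal excess exceeds the 95th
percentile of the same statistic scored for each CSR iteration against the
CSR mean; because the null statistic is maximized exactly as the observed
one is, the gate's false-positive rate is calibrated (~5%), and CSR inputs
are reported as "no clustering detected" with an `NA` threshold.

`segmentClusters()` rasterizes the first-rank Voronoi density (1 / polygon
area; no neighbour-rank averaging) onto 10-nm pixels of candidate
(sub-threshold) polygons, smooths with a 3-pixel (30-nm) Gaussian, and
applies watershed segmentation restricted to the candidate support, with
tolerance 0.1 on the max-normalized map. The smoothing scale was chosen to
fuse the per-polygon granularity of the density map while preserving the
density dip between abutting clusters; heavier smoothing visibly merges
clusters planted ~300-400 nm apart, and lighter smoothing fragments single
clusters into their constituent polygons. Segments smaller than 10 pixels
are excluded, and segments containing fewer than 5 localizations (the same
count used by the density filter) are also excluded: chance pairs of
background localizations can pass the area threshold, and a
localization-count floor removes them without touching genuine clusters,
which carry tens of localizations. Per-cluster statistics are pixel area,
equivalent diameter `2*sqrt(area/pi)`, localization count, and centroid;
field summaries are clusters per um^2, fractional area occupied, and
medians. Percent change between two summaries is `(a - b)/a * 100`, rounded
to the nearest integer percent.

`particleAnalysis()` is the independent cross-check: 8-connected component
labelling of a binary map rendered from the same localizations, with the
same size filter and summaries. On densely sampled, well-separated fields
the two segmentations agree in cluster count within ±2; on sparsely sampled
fields (tens of localizations per cluster) the raw binary map fragments and
particle analysis is not meaningful without prior gap-filling — the
junction-mask dilation exists for exactly that case.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions used by every stochastic test:

* **Two-state tracks** (`simulateTwoStateTracks()`): molecules are free
  (default D = 0.084 um^2/s, the on-junction free-ORAI1 reference) or bound
  (default D = 0.0394 um^2/s, the STIM1 reference), with a default bound
  fraction of 0.84. States are static per molecule unless switching rates
  are supplied (applied per substep). Bound molecules reflect at their
  junction disc (default radius 160 nm); reflection is radial
  (`r -> 2R - r`), accurate when per-substep steps are small relative to
  the disc — with the default 10 substeps per 50-ms frame, steps are
  ~30-40 nm against R = 160 nm. Reported positions average the substep
  positions within each frame (continuous-illumination motion blur;
  empirically the single-step MSD contracts to 2/3, matching the closed
  form the 1.5 factor assumes) and add independent per-axis Gaussian error
  (default 46 nm). Track lengths are uniform on 7-26 frames, matching the
  6-25-step excursion window.
* **Stationary emitters** (`simulateFixedEmitters()`): the fixed-cell
  calibration control; MSD1 estimates `4*sigma_axis^2` (0.00846 um^2 at
  46 nm).
* **Cluster fields** (`simulateClusterField()`): 17 cluster centers uniform
  in a 4 x 4 um ROI (inset so discs fit), 32 localizations uniform in a
  200-nm disc per center — or 100 in a 400-nm disc — each jittered by an
  isotropic Gaussian of 70 nm per axis, plus background at exactly
  `round(0.007 * nPixels)` distinct 10-nm pixels (pixel center plus
  sub-pixel jitter, no additional uncertainty). The background count is
  deterministic rather than Bernoulli-per-pixel, which eases exact count
  assertions at a negligible distributional difference. Gaussian jitter is
  re-drawn until the point falls inside the ROI, keeping counts exact; the
  32<->200-nm and 100<->400-nm pairings keep surface density comparable.
* **Dual-channel fields** (`simulateDualChannelField()`): red localizations
  with planted density ratio e between the inside and outside of a
  territory mask, normalized to the requested total — the ground truth for
  NCG recovery.

These generators reproduce the *statistical* structure the estimators rely
on, not the photophysics of real acquisitions: no blinking kinetics, photon
budgets, camera noise, detection misses in dense regions, or 3D motion.
Passing tests therefore demonstrate correctness of the estimators under the
stated model, not robustness to every artifact of real data.

A note on uniform center placement: with 17 centers placed uniformly at
random in 16 um^2, a few center pairs typically fall within one disc
diameter of each other and their localization clouds genuinely merge.
Recovered cluster counts on the 200-nm reference fields therefore scatter
around 17 (mean within ±2 over seeds) rather than hitting it exactly, and
the same uniform placement makes the 400-nm/100-localization fields
over-segment (apparent substructure), never undercount — both behaviours
are asserted in the tests.

## Problem sizes and runtime choices

The test suite and the reproduction script favour sizes that keep each
stochastic check's sampling error well inside its tolerance: 40,000
stationary emitters for the calibration reproduction (relative SEM ~0.5%),
2,500 x 12-frame tracks for blur-factor validation, 1,500 tracks per
condition for engagement recovery (the conventional per-condition sample),
10 seeds x 100 Monte-Carlo iterations for the cluster-count reproduction,
and 40-100 Monte-Carlo iterations in module tests where only detection, not
the precise threshold, is under test.

## Known limitations

* MSD SEMs ignore interval correlation (overlapping intervals).
* NCG saturates at high per-pixel occupancy; it is a pixel statistic.
* The engagement estimator is ensemble-level; it does not segment
  individual trajectories into states.
* Radial reflection is a small-step approximation to specular reflection.
* The Voronoi threshold convention (histogram crossing) balances
  misclassification of cluster and background localizations; with heavy
  background some background pairs pass the area threshold, which the
  localization-count floor, not the threshold itself, removes.
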