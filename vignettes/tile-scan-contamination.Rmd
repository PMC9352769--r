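---
title: "Measuring particulate surface contamination from tile-scan microscopy"
author: "ParticleScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring particulate surface contamination from tile-scan microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ParticleScan)
```

## The measurement problem

Long-duration crewed spacecraft keep their cabin air in laminar circulation,
and airborne particles — skin flakes, fibres, mineral dust, and droplets
carrying microbial cells — slowly deposit on every exposed surface. The
MATISS exposure experiments quantified this deposition on hydrophobic
(FDTS-coated) glass coupons flown in the Columbus module of the ISS: coupons
sat behind a slit holder for months, were returned sealed, and each 8 x 8 mm
observation window was tile-scanned by brightfield optical microscopy at two
magnifications. Low zoom (here 2.2 um/px by default) resolves the *coarse*
particle fraction, 50–1500 um^2 of projected area; high zoom (0.22 um/px)
resolves the *fine* fraction, 0.5–50 um^2, whose rounded and constricted
("bacteriomorph") outlines are consistent with single cocci and division
figures. Objects above 1500 um^2 are *macroscopic*; detections below 0.5
um^2 are kept but flagged *subresolution*.

The quantities of interest are per-window particle densities
(particles/mm^2) by size class, the particle size distribution and its mode,
the deposition profile along the air-flow axis, the accumulation kinetics
over exposure time (and the derived area-coverage rate in %/year), and how
the contamination rate theta varies with the module occupancy rate eta.

The flight images themselves are not publicly deposited. The package
therefore pairs the analysis chain with a synthetic tile-scan generator that
carries a full ground truth, so every stage is verifiable in closed loop:
campaign values seeded into the generator must be recovered by the complete
pipeline (render, segment, refine, classify, summarise).

## The segmentation chain

Processing follows the published two-zoom, two-pass procedure.

1. **Channel extraction.** Segmentation at both zooms runs on the blue
   component of the RGB frames (the blue channel carries the deepest
   contrast under the acquisition gains); refinement crops at high zoom are
   sampled from the 8-bit grey-scale average of the RGB frames. Inputs
   deeper than 8 bits are rescaled to the 8-bit working depth.
2. **Low zoom: constant threshold.** Pixels darker than a constant grey
   level (default 75, configurable) are particle candidates.
3. **High zoom: shadow-frame rejection, then a stack threshold.** Frames in
   which a macroscopic object's shadow masks the small particles are
   removed *before* the stack statistics are computed: a frame is rejected
   when its fraction of pixels darker than a provisional background
   threshold exceeds `rejectDarkFraction` (default 0.10, validated against
   the generator's shadow bookkeeping). The stack threshold is the
   background median incremented by k (default 2) times the mean per-frame
   standard deviation of the stack intensity. Because particles are *darker*
   than the background, the statistic is applied on the darkness
   (inverted-grey) scale, where particles exceed the threshold; on the grey
   scale this is a threshold of median − k × mean SD. Applied directly on
   the grey scale, a median-plus-2-SD cut would sit above ~97% of the
   background and could not discriminate at all — the darkness-scale reading
   is the only orientation under which the published statistic segments
   dark objects, and `computeStackThreshold()` implements (and is tested
   against) the formula verbatim.
4. **First pass.** Connected components of sub-threshold pixels
   (8-connectivity by default, the Analyze-Particles convention;
   4-connectivity available) with at least `minAreaPx` pixels (default 8).
   Centroids are mapped to window coordinates through the frame-origin map.
5. **Refinement.** A crop centred on each detection — half-width twice the
   equivalent radius plus a margin — is re-segmented at a local threshold,
   crop mean − c × crop SD (c = 1.5 by default), floored at the global
   threshold minus a guard band (30 grey levels). The component containing
   the crop centre is retained if it overlaps the first-pass mask by at
   least 50%; detections lost at the local threshold are *flagged*, never
   silently dropped. The published description states only that the local
   threshold is "a function of the mean value" of the crop and that the
   crop uses the central particle's area; the specific form here is a
   documented package choice that degenerates gracefully on flat crops.
   Refinement runs at both zooms by default (the compiled-positions wording
   suggests crops were sampled from both stacks); `refineLowZoom = FALSE`
   restricts it to high zoom.

Elongation is the fitted-ellipse major/minor axis ratio computed from the
mask's central second moments (a 1/12-pixel variance keeps single pixels
finite); area is the refined pixel count times the pixel area; classes are
assigned on half-open, lower-inclusive intervals, so a tie at 50 um^2 goes
coarse — the published captions use strict inequalities on both sides, which
leaves boundary points unassigned, so an explicit (configurable) convention
is required.

### The detection floor and false positives

With a threshold at 2 SD below the background median, ~2% of pure-noise
pixels are dark by construction, regardless of the noise level. Isolated
dark pixels are harmless, but small 8-connected noise clusters do occur,
and their abundance falls steeply with cluster size. The default
`minAreaPx = 8` sits above that cluster tail while remaining below the
smallest in-class particle at the default calibrations (0.5 um^2 is ~10 px
at 0.22 um/px; 50 um^2 is ~10 px at 2.2 um/px), and refinement removes most
survivors. The test suite bounds the resulting end-to-end false-positive
rate on particle-free synthetic windows at a small fraction of the fine
densities of 1–5/mm^2.

## The synthetic campaign generator

`campaignConfig()` describes one exposure campaign; `simulateWindow()`
draws a window. The generator emulates:

* **Poisson deposition.** Per-class counts are Poisson with mean density ×
  window area — the independence assumption appropriate for dilute aerosol
  deposition. Densities are *seeded*, i.e. they are the study conditions,
  not free dials.
* **Bimodal size structure.** Log-normal size models clipped to the class
  supports: coarse mode 155 um^2 (sdlog 0.5) on [50, 1500); fine mode 3
  um^2 (sdlog 1) on [0.5, 50) — bacteriomorph-scale, consistent with cells
  and microcolonies under ~20 um^2; macroscopic mode 8.2 × 10^4 um^2
  (sdlog 0.3). The meanlog is set so the untruncated mode equals the
  configured mode.
* **Shape families.** Fine: cocci (discs), dividing cocci rendered as two
  overlapping discs with a constriction plus a faint evaporation halo (an
  annulus ~6 grey levels below background, deliberately *not* part of the
  ground-truth area, and separated from the body so it cannot merge into
  the detection), and short fibres. Coarse: hexagonal scale discs, fibres,
  angular crystals (convex jittered polygons) and parallelepipedic
  aggregates (overlapping rotated rectangles). Rasterisation binary-searches
  the linear scale so the pixel count matches the nominal area (within 5%
  from 20 px up, and the ground-truth area records the rendered count
  exactly); a deterministic sub-pixel centre offset breaks the count
  quantisation of pixel-centred shapes.
* **Flow-axis gradients.** Particle y-positions follow an exponential
  density exp(−s·y/H) along the flow axis (aperture at y = 0); positive s
  concentrates particles toward the aperture. The published maps show
  coarse particles accumulated near the aperture and fine particles away
  from it, with no functional form stated; the packaged configs use
  s = +1.5 (coarse) and −1.5 (fine), free parameters.
* **Macroscopic objects and shadows.** Rare large objects (Poisson per
  window) render at high zoom with a deep circular shadow of three times
  their radius, the trigger for frame rejection; the generator reports
  which frames the dark core covers (>= 10% of the frame) so rejection can
  be validated. At low zoom the same objects image cleanly, as in the
  flight mosaics.
* **Background.** Gaussian noise (SD 5 grey levels) on a bright background
  (200), quantised to 8 bits; particles stamp dark (level 60 at low zoom,
  130 at high zoom). The red and green channels carry the same scene
  slightly brighter, so the blue component has the deepest contrast and the
  grey average is well defined. Acquisition RGB gains are treated as
  metadata, not simulated.

Rendering is deterministic given the R seed: per-frame noise seeds are
drawn once from the R stream, and *lazy* stacks re-render frames on access
bit-identically, which keeps memory flat at any tile count.

### Packaged reference campaigns

`referenceConfig()` seeds the printed per-window mean densities of each
campaign/timepoint — coarse 2.45 (MATISS-1, 193 d), 2.01 (MATISS-2, 354 d),
0.36 (MATISS-2.5, 365 d); fine 4.45, 4.68, 1.02, and 3.82 at the MATISS-2
95-day timepoint — together with eta = 1.0 for the high-occupancy exposures
and 0.35 for the low-occupancy ones. The unprinted intermediate MATISS-2
values lie on the linear accumulation through the printed points (coarse
through the origin; fine keeps its fitted intercept, as its kinetics are
visibly shallower).

The macroscopic model deserves a note. The published coverage rate of
~0.5%/year for the 354-day campaign cannot arise from the coarse class
alone: at 2.01 particles/mm^2 with areas strictly below 1500 um^2 the
ceiling is ~0.31%/year, and the realistic coarse mean area (~370 um^2)
gives ~0.07%/year. Coverage at that level must be carried by the rare
macroscopic objects (the flight mosaics show several-hundred-micrometre
examples). The package therefore computes coverage over all detected
classes by default, and the MATISS-2 macroscopic model (3 objects per
window, mean ~9.4 × 10^4 um^2) is derived once, analytically, from the
printed 0.5%/year given the other printed values. This is the one place a
reference parameter is calibrated to a printed *rate* rather than a printed
*density*.

## Statistics

* `windowDensity()` is an exact count/area; `densitySummary()` reports the
  mean and sample SD (n − 1) across windows — the dot-plot centerlines and
  error bars.
* `sizeDistribution()` builds equal-width histograms (defaults 50 um^2
  coarse, 2.5 um^2 fine — bin widths are not stated in the figures) with a
  cumulative curve normalised to the class total; the mode is the midpoint
  of the maximal bin.
* `spatialProfile()` bins positions along the flow axis and reports the
  asymmetry index (N_far − N_near)/(N_far + N_near), an invented but
  standard normalised difference anchored to the aperture-at-0 convention:
  negative means accumulation near the aperture. It is exactly antisymmetric
  under reflection and reported as missing (never 0) for empty scopes.
* `fitKinetics()` fits density on exposure days by weighted least squares
  (weights 1/SE^2), intercept fitted rather than forced through zero since
  the published curves are only "almost linear"; a forced-zero variant and
  an unweighted fallback (zero SEs) exist.
* `coverageRate()` is (sum of particle areas)/(window area) × 100 ×
  365/exposure days, per class or overall.
* `rateVsOccupancy()` tabulates (eta, theta) pairs — theta is the fitted
  slope where kinetics exist, density/exposure otherwise — and checks
  monotonicity; no functional form is fitted because the published
  association is shown only with guide-eye curves.

## Desk-scale problem sizes

Flight acquisition used 30 low-zoom and 1452 high-zoom frames per window;
`imagingPreset("full")` reproduces that geometry. All tests and the
acceptance script run the `"desk"` preset: a full-height strip of the
window tiled by 4 (low zoom) or 16 (high zoom) frames. Full-height strips
make y-gradients average out of density estimates exactly, and the imaged
(retained-frame) area is always the density denominator. The closed-loop
campaign checks use 20 replicate windows per campaign; high-zoom runs use
0.35 um/px — still >= 4 pixels on the smallest 0.5 um^2 particle, the
resolvability floor — with strip widths chosen so each campaign accumulates
several hundred particles (the estimator SD is then a few percent, dominated
by Poisson counting). The coverage check uses 40 full-window low-zoom
replicates because its variance is driven by the ~3 macroscopic objects per
window. The sparsest campaign (MATISS-2.5) gets proportionally wider strips.

## What passing these checks does and does not show

The generator reproduces the statistical structure the analysis assumes:
Poisson counts, right-skewed size spectra, distinct shape families, smooth
background noise, exponential flow-axis gradients, and shadow-casting
macroscopic objects. It does not emulate focus drift, illumination
flat-field error, stitching misregistration between tiles, overlapping or
aggregated particles at high density, sub-resolution texture inside
particles, or the chemistry of the coating itself. Recovery of seeded
values therefore validates the pipeline's correctness and calibration
logic, not its robustness to every artefact of flight imagery. Particles
whose raster straddles internal frame boundaries are segmented per frame
(no stitching, by design), a ~0.5% double-counting effect at the default
geometries; window-edge clipping is similarly sub-percent.

## Worked example

```{r example, eval = FALSE}
library(ParticleScan)
set.seed(1)

cfg <- referenceConfig("MATISS-2", 354)
sim <- simulateWindow(cfg, zoom = "low", lazy = TRUE)
wr <- analyzeStack(sim$stack)
wr
windowDensity(wr, "coarse")

res <- runPipeline(cfg, zoom = "low", nWindows = 5, seed = 1)
res$summaries$coarse[c("mean", "sd", "n")]
```
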