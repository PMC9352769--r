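#' @useDynLib ParticleScan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

SHAPE_FAMILIES <- c("coccus", "dividing_coccus_with_halo", "hexagonal_disc",
                    "fiber", "angular_crystal", "parallelepiped_aggregate")

#' CampaignConfig: generator and analysis parameters for one exposure campaign
#'
#' Bundles everything needed to simulate (and later analyse) one coupon-window
#' exposure campaign: exposure duration, module occupancy rate, seeded
#' per-class particle densities, the size models for the fine and coarse
#' fractions, shape-family mixtures, an optional density gradient along the
#' flow (y) axis, the background noise level, imaging geometry and the seed.
#'
#' @slot name Character label for the campaign.
#' @slot exposureDays Exposure duration in days (> 0).
#' @slot occupancyRate Module occupancy rate eta, fraction in [0, 1].
#' @slot coarseDensity,fineDensity Seeded particle densities, particles/mm^2.
#' @slot macroRate Expected number of macroscopic (> 1500 um^2) objects per
#'   8 x 8 mm window.
#' @slot sizeModelCoarse,sizeModelFine,sizeModelMacro Named lists
#'   \code{list(family = "lognormal", mode = <um^2>, sdlog = <..>,
#'   support = c(lo, hi))}; sampling is clipped to the half-open support.
#' @slot shapeMixCoarse,shapeMixFine Named numeric proportions over the shape
#'   families, each summing to 1.
#' @slot gradient List \code{list(type = "none"|"linear"|"exponential",
#'   strengthCoarse =, strengthFine =)}; positive strength concentrates
#'   particles towards the aperture side (y = 0), negative away from it.
#' @slot noiseSd Background grey-level standard deviation.
#' @slot imaging List of imaging geometry: \code{pixelSizeLow},
#'   \code{pixelSizeHigh} (um/px), \code{windowUm} (window side, um),
#'   \code{stripWidthLowUm}, \code{stripWidthHighUm} (imaged strip widths),
#'   \code{framesLow}, \code{framesHigh} (frames along the strip),
#'   \code{background}, \code{particleLevelLow}, \code{particleLevelHigh},
#'   \code{haloDepth} (grey levels).
#' @slot seed Integer seed.
#' @export
setClass("CampaignConfig", representation(
  name = "character", exposureDays = "numeric", occupancyRate = "numeric",
  coarseDensity = "numeric", fineDensity = "numeric", macroRate = "numeric",
  sizeModelCoarse = "list", sizeModelFine = "list", sizeModelMacro = "list",
  shapeMixCoarse = "numeric", shapeMixFine = "numeric", gradient = "list",
  noiseSd = "numeric", imaging = "list", seed = "numeric"))

setValidity("CampaignConfig", function(object) {
  msg <- character()
  if (object@exposureDays <= 0) msg <- c(msg, "exposureDays must be > 0")
  if (object@occupancyRate < 0 || object@occupancyRate > 1)
    msg <- c(msg, "occupancyRate must lie in [0, 1]")
  if (min(object@coarseDensity, object@fineDensity, object@macroRate) < 0)
    msg <- c(msg, "densities and macroRate must be >= 0")
  for (nm in c("sizeModelCoarse", "sizeModelFine", "sizeModelMacro")) {
    sm <- slot(object, nm)
    if (!all(c("mode", "sdlog", "support") %in% names(sm)))
      msg <- c(msg, paste(nm, "needs mode, sdlog and support"))
    else if (sm$support[1] >= sm$support[2])
      msg <- c(msg, paste(nm, "support must be an increasing interval"))
  }
  for (nm in c("shapeMixCoarse", "shapeMixFine")) {
    mix <- slot(object, nm)
    if (!all(names(mix) %in% SHAPE_FAMILIES))
      msg <- c(msg, paste(nm, "has unknown shape families"))
    if (abs(sum(mix) - 1) > 1e-8)
      msg <- c(msg, paste(nm, "proportions must sum to 1"))
  }
  if (!object@gradient$type %in% c("none", "linear", "exponential"))
    msg <- c(msg, "gradient type must be none, linear or exponential")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CampaignConfig", function(object) {
  cat("CampaignConfig '", object@name, "': ", object@exposureDays,
      " days, eta = ", object@occupancyRate, "\n", sep = "")
  cat("  densities (per mm^2): coarse ", object@coarseDensity, ", fine ",
      object@fineDensity, "; macro/window ", object@macroRate, "\n", sep = "")
  cat("  gradient: ", object@gradient$type, " (coarse ",
      object@gradient$strengthCoarse, ", fine ",
      object@gradient$strengthFine, "); seed ", object@seed, "\n", sep = "")
})

#' FrameStack: an ordered tile-scan stack of RGB frames for one window
#'
#' Frames are integer arrays (rows = y, columns = x, 3 channels R/G/B) sharing
#' dimensions and bit depth. The frame-origin map places each frame in window
#' coordinates (um; the aperture side of the window is at y = 0 and y grows
#' along the air-flow path). Stacks may be lazy: frames are then re-rendered
#' deterministically on access from the stored generator spec and per-frame
#' seeds, which keeps desk-scale memory flat while preserving bit-identical
#' pixels.
#'
#' @slot frames List of integer arrays (may be empty for lazy stacks).
#' @slot zoom "low" or "high".
#' @slot pixelSize um per pixel.
#' @slot frameDim Integer c(rows, cols) shared by all frames.
#' @slot frameOrigins data.frame(frame, x0_um, y0_um) of frame origins.
#' @slot bitDepth Bits per channel (8 or 12).
#' @slot windowUm Window side length, um.
#' @slot generator List with the deterministic render spec for lazy stacks
#'   (truth table, config, per-frame seeds, macro objects), or empty.
#' @slot metadata Free-form list (exposure metadata etc.).
#' @export
setClass("FrameStack", representation(
  frames = "list", zoom = "character", pixelSize = "numeric",
  frameDim = "integer", frameOrigins = "data.frame", bitDepth = "numeric",
  windowUm = "numeric", generator = "list", metadata = "list"))

setValidity("FrameStack", function(object) {
  msg <- character()
  if (!object@zoom %in% c("low", "high")) msg <- c(msg, "zoom must be low/high")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@frames)) {
    dims <- vapply(object@frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
    if (length(unique(dims)) != 1L)
      msg <- c(msg, "all frames must share dimensions")
  }
  if (nrow(object@frameOrigins) == 0L)
    msg <- c(msg, "frameOrigins must have at least one frame")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrameStack", function(object) {
  cat("FrameStack: ", nrow(object@frameOrigins), " frame(s) at ", object@zoom,
      " zoom, ", object@frameDim[1], "x", object@frameDim[2], " px, ",
      object@pixelSize, " um/px, ", object@bitDepth, "-bit",
      if (length(object@generator)) " (lazy)" else "", "\n", sep = "")
})

#' SegmentationConfig: parameters of the two-pass segmentation
#'
#' @slot lowZoomThreshold Constant grey-level threshold for the low zoom pass.
#' @slot highZoomK Multiplier k of the mean per-frame SD in the stack
#'   threshold statistic.
#' @slot rejectDarkFraction Fraction of sub-threshold pixels above which a
#'   high-zoom frame is rejected as shadowed.
#' @slot localThresholdC Multiplier c in the crop-local threshold
#'   (crop mean - c * crop SD).
#' @slot guardBand Grey levels; the local threshold is floored at the global
#'   threshold minus this band.
#' @slot cropMarginPx Margin added to twice the equivalent radius when sizing
#'   refinement crops.
#' @slot minAreaPx Detection floor in pixels.
#' @slot connectivity 4 or 8.
#' @slot overlapMin Minimum fractional overlap of the refined component with
#'   the first-pass mask for a detection to stay refined.
#' @slot refineLowZoom Whether the low-zoom pass is also crop-refined.
#' @export
setClass("SegmentationConfig", representation(
  lowZoomThreshold = "numeric", highZoomK = "numeric",
  rejectDarkFraction = "numeric", localThresholdC = "numeric",
  guardBand = "numeric", cropMarginPx = "numeric", minAreaPx = "numeric",
  connectivity = "numeric", overlapMin = "numeric", refineLowZoom = "logical"))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@lowZoomThreshold < 0 || object@lowZoomThreshold > 4095)
    msg <- c(msg, "lowZoomThreshold outside representable grey range")
  if (object@highZoomK <= 0) msg <- c(msg, "highZoomK must be > 0")
  if (object@rejectDarkFraction < 0 || object@rejectDarkFraction > 1)
    msg <- c(msg, "rejectDarkFraction must lie in [0, 1]")
  if (!object@connectivity %in% c(4, 8))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (object@minAreaPx < 1) msg <- c(msg, "minAreaPx must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig: low-zoom threshold ", object@lowZoomThreshold,
      ", high-zoom k ", object@highZoomK, ", reject dark fraction ",
      object@rejectDarkFraction, ",\n  local threshold c ",
      object@localThresholdC, ", min area ", object@minAreaPx,
      " px, connectivity ", object@connectivity, "\n", sep = "")
})

#' WindowResult: calibrated particles and densities for one window
#'
#' @slot windowId Window identifier.
#' @slot imagedAreaMm2 Imaged (retained-frame) area in mm^2, the denominator
#'   of all densities.
#' @slot particles data.frame of calibrated particles (x_um, y_um, area_um2,
#'   elongation, mean_intensity, size_class).
#' @slot exposureDays Exposure duration carried along for kinetics.
#' @export
setClass("WindowResult", representation(
  windowId = "character", imagedAreaMm2 = "numeric", particles = "data.frame",
  exposureDays = "numeric"))

setValidity("WindowResult", function(object) {
  if (object@imagedAreaMm2 <= 0) "imagedAreaMm2 must be > 0" else TRUE
})

setMethod("show", "WindowResult", function(object) {
  tab <- table(object@particles$size_class)
  cat("WindowResult '", object@windowId, "': ", nrow(object@particles),
      " particle(s) on ", round(object@imagedAreaMm2, 3), " mm^2 (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      ")\n", sep = "")
})

#' SizeDistribution: histogram and cumulative curve of particle areas
#' @slot binEdges Bin edges, um^2 (half-open bins [e_i, e_{i+1})).
#' @slot counts Counts per bin.
#' @slot cumulativeFraction Non-decreasing cumulative fraction per bin.
#' @slot sizeClass Size class summarised.
#' @export
setClass("SizeDistribution", representation(
  binEdges = "numeric", counts = "numeric", cumulativeFraction = "numeric",
  sizeClass = "character"))

setMethod("show", "SizeDistribution", function(object) {
  cat("SizeDistribution (", object@sizeClass, "): ", sum(object@counts),
      " particle(s) in ", length(object@counts), " bins of width ",
      object@binEdges[2] - object@binEdges[1], " um^2; mode bin midpoint ",
      modeBin(object), "\n", sep = "")
})

#' SpatialProfile: particle counts along the flow (y) axis
#' @slot yBinEdges Bin edges along y, um (aperture side at 0).
#' @slot counts Counts per bin.
#' @slot asymmetryIndex (N_far - N_near) / (N_far + N_near); NA when empty.
#' @export
setClass("SpatialProfile", representation(
  yBinEdges = "numeric", counts = "numeric", asymmetryIndex = "numeric"))

setMethod("show", "SpatialProfile", function(object) {
  cat("SpatialProfile: ", sum(object@counts), " particle(s) in ",
      length(object@counts), " y-bins; asymmetry index ",
      signif(object@asymmetryIndex, 3), "\n", sep = "")
})

#' KineticsFit: weighted linear accumulation-rate estimate
#' @slot slope particles/mm^2/day.
#' @slot intercept particles/mm^2.
#' @slot slopeSE Standard error of the slope.
#' @slot weighted Whether 1/SE^2 weights were used (FALSE = unweighted
#'   fallback when an SE was zero or missing).
#' @slot points The fitted (days, density, SD, n) table.
#' @export
setClass("KineticsFit", representation(
  slope = "numeric", intercept = "numeric", slopeSE = "numeric",
  weighted = "logical", points = "data.frame"))

setMethod("show", "KineticsFit", function(object) {
  cat("KineticsFit: slope ", signif(object@slope, 4),
      " /mm^2/day (SE ", signif(object@slopeSE, 3), "), intercept ",
      signif(object@intercept, 4), if (!object@weighted)
        " [unweighted fallback]", "\n", sep = "")
})
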