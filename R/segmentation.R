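## Two-zoom, two-pass segmentation: constant threshold at low zoom, stack
## statistic at high zoom, shadow-frame rejection, connected components and
## crop-centred local refinement.

#' Construct a SegmentationConfig
#'
#' Defaults follow the published procedure where stated (constant low-zoom
#' grey threshold 75; stack statistic with k = 2 at high zoom) and documented
#' package choices elsewhere (dark-pixel-fraction shadow rejection at 0.10;
#' local threshold crop mean - 1.5 x crop SD floored at the global threshold
#' minus a 30-grey-level guard band; 8-connectivity; detection floor 8 px,
#' below the smallest in-class particle at the default calibrations).
#'
#' @param lowZoomThreshold Constant grey threshold for the low-zoom pass.
#' @param highZoomK SD multiplier k in the stack threshold.
#' @param rejectDarkFraction Dark-pixel fraction above which a high-zoom
#'   frame is rejected.
#' @param localThresholdC Multiplier c of the crop SD in refinement.
#' @param guardBand Guard band (grey levels) flooring the local threshold.
#' @param cropMarginPx Margin added to 2 x equivalent radius for crop sizing.
#' @param minAreaPx Detection floor, pixels.
#' @param connectivity 4 or 8.
#' @param overlapMin Minimum refined/first-pass mask overlap fraction.
#' @param refineLowZoom Refine the low-zoom pass too (default TRUE).
#' @return A validated \linkS4class{SegmentationConfig}.
#' @export
segmentationConfig <- function(lowZoomThreshold = 75, highZoomK = 2,
                               rejectDarkFraction = 0.10,
                               localThresholdC = 1.5, guardBand = 30,
                               cropMarginPx = 6, minAreaPx = 8,
                               connectivity = 8, overlapMin = 0.5,
                               refineLowZoom = TRUE) {
  new("SegmentationConfig", lowZoomThreshold = lowZoomThreshold,
      highZoomK = highZoomK, rejectDarkFraction = rejectDarkFraction,
      localThresholdC = localThresholdC, guardBand = guardBand,
      cropMarginPx = cropMarginPx, minAreaPx = minAreaPx,
      connectivity = connectivity, overlapMin = overlapMin,
      refineLowZoom = refineLowZoom)
}

## rescale a channel matrix to the 8-bit working depth
.toWorkingDepth <- function(m, bitDepth) {
  if (bitDepth == 8) return(m)
  matrix(as.integer(round(m * 255 / (2^bitDepth - 1))), nrow(m), ncol(m))
}

.blueChannel <- function(frame, bitDepth = 8) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frames must be RGB (rows x cols x 3)")
  .toWorkingDepth(frame[, , 3L], bitDepth)
}

.grayChannel <- function(frame, bitDepth = 8) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    stop("frames must be RGB (rows x cols x 3)")
  g <- round((frame[, , 1L] + frame[, , 2L] + frame[, , 3L]) / 3)
  .toWorkingDepth(g, bitDepth)
}

## blue channel of frame i without materialising RGB for generated stacks
.stackBlue <- function(stack, i) {
  if (length(stack@generator))
    renderFrameBlue(stack@generator$truth, stack@generator$config,
                    stack@zoom, stack, i, stack@generator$frameSeeds[i])
  else .blueChannel(getFrame(stack, i), bitDepth(stack))
}

#' Extract a working single-channel stack from RGB frames
#'
#' Segmentation at both zoom levels runs on the blue component; refinement
#' crops at high zoom are sampled from the 8-bit grey-scale average of the
#' RGB frames. Inputs deeper than 8 bits are rescaled to the 8-bit working
#' depth.
#'
#' @param stack A FrameStack (frames are materialised as needed).
#' @param channel "blue" or "gray".
#' @return List of integer matrices, one per frame.
#' @export
extractChannel <- function(stack, channel = c("blue", "gray")) {
  channel <- match.arg(channel)
  fun <- if (channel == "blue") .blueChannel else .grayChannel
  lapply(seq_len(nFrames(stack)), function(i)
    fun(getFrame(stack, i), bitDepth(stack)))
}

## exact integer-histogram summaries (counts over grey levels 0..nlev-1)
.frameHist <- function(m, nlev = 256L) tabulate(m + 1L, nbins = nlev)

.histMedian <- function(counts) {
  n <- sum(counts)
  if (!n) stop("empty stack")
  cs <- cumsum(counts)
  lo <- which(cs >= ceiling(n / 2))[1] - 1L
  if (n %% 2 == 1) return(as.numeric(lo))
  hi <- which(cs >= n / 2 + 1)[1] - 1L
  (lo + hi) / 2
}

.histSD <- function(counts) {
  n <- sum(counts)
  v <- seq_along(counts) - 1
  s1 <- sum(counts * v)
  s2 <- sum(counts * v * v)
  sqrt((s2 - s1 * s1 / n) / (n - 1))
}

#' Stack threshold statistic: median plus k times the mean per-frame SD
#'
#' Computes median(all pixels of the stack) + k x mean over frames of the
#' per-frame intensity standard deviation. The statistic is taken on
#' whatever intensity scale the frames are given in; in the high-zoom
#' pipeline it is applied on the darkness (inverted-grey) scale so that dark
#' particles exceed it (see \code{\link{runSegmentation}}).
#'
#' @param frames List of single-channel matrices (>= 1 frame), or a list of
#'   per-frame integer histograms via the \code{hists} argument.
#' @param k SD multiplier.
#' @param hists Optional list of per-frame histograms replacing frames.
#' @return The threshold (numeric scalar).
#' @export
computeStackThreshold <- function(frames, k = 2, hists = NULL) {
  if (is.null(hists)) {
    if (!length(frames)) stop("empty stack")
    allInt <- all(vapply(frames, function(f) is.integer(f) ||
                           all(f == round(f)), TRUE))
    if (allInt && all(vapply(frames, function(f)
      min(f) >= 0 && max(f) < 4096, TRUE))) {
      hists <- lapply(frames, .frameHist, nlev = 4096L)
    } else {
      med <- stats::median(unlist(frames, use.names = FALSE))
      return(med + k * mean(vapply(frames, stats::sd, 1)))
    }
  }
  if (!length(hists)) stop("empty stack")
  .histMedian(Reduce(`+`, hists)) + k * mean(vapply(hists, .histSD, 1))
}

#' Reject shadowed frames from a high-zoom stack
#'
#' A frame is rejected when its fraction of pixels darker than a provisional
#' background threshold (the stack statistic over all frames, applied on the
#' darkness scale) exceeds \code{rejectDarkFraction}. Rejection happens
#' before the final stack threshold is computed so rejected frames never
#' contaminate the stack statistics; retained frames are returned untouched.
#'
#' @param frames List of single-channel (blue) matrices.
#' @param cfg A SegmentationConfig.
#' @param maxval Maximum representable grey level of the working depth.
#' @return list(retained = indices, rejected = indices). An error condition
#'   where every frame is rejected is signalled via a warning and an empty
#'   retained set.
#' @export
rejectShadowFrames <- function(frames, cfg = segmentationConfig(),
                               maxval = 255) {
  hists <- lapply(frames, .frameHist, nlev = maxval + 1L)
  res <- .rejectFromHists(hists, cfg, maxval)
  if (!length(res$retained))
    warning("all frames rejected as shadowed; retained stack is empty")
  res
}

.rejectFromHists <- function(hists, cfg, maxval = 255) {
  inv <- lapply(hists, rev)  # histogram on the darkness scale
  thrD <- computeStackThreshold(NULL, cfg@highZoomK, hists = inv)
  provisional <- maxval - thrD  # grey level below which a pixel is "dark"
  darkFrac <- vapply(hists, function(h) {
    n <- sum(h)
    lev <- which(seq_along(h) - 1 < provisional)
    if (length(lev)) sum(h[lev]) / n else 0
  }, 1)
  rejected <- which(darkFrac > cfg@rejectDarkFraction)
  list(retained = setdiff(seq_along(hists), rejected), rejected = rejected,
       provisionalThreshold = provisional, darkFraction = darkFrac)
}

## ellipse axis ratio from central second moments (1/12 px variance added so
## single pixels have unit extent)
.elongation <- function(mu_xx, mu_yy, mu_xy) {
  a <- mu_xx + 1 / 12
  b <- mu_yy + 1 / 12
  disc <- sqrt(pmax((a - b)^2 + 4 * mu_xy^2, 0))
  l1 <- (a + b + disc) / 2
  l2 <- pmax((a + b - disc) / 2, 1e-9)
  sqrt(l1 / l2)
}

#' First-pass segmentation of a stack at a fixed threshold
#'
#' Connected components of sub-threshold (dark) pixels at the configured
#' connectivity, with pixel area >= minAreaPx; centroids are mapped to window
#' coordinates through the frame-origin map.
#'
#' @param stack A FrameStack.
#' @param threshold Grey-level threshold (pixels strictly below are dark).
#' @param cfg A SegmentationConfig.
#' @param frameIndices Frames to process (default all).
#' @param blueFrames Optional pre-extracted blue matrices (same order as
#'   \code{frameIndices}).
#' @return Detection data.frame (one row per component) with pixel and window
#'   coordinates, pixel area, moments, mean intensity and bounding box.
#' @export
firstPassSegment <- function(stack, threshold, cfg = segmentationConfig(),
                             frameIndices = seq_len(nFrames(stack)),
                             blueFrames = NULL) {
  out <- vector("list", length(frameIndices))
  px <- pixelSize(stack)
  fo <- frameOrigins(stack)
  for (j in seq_along(frameIndices)) {
    i <- frameIndices[j]
    blue <- if (!is.null(blueFrames)) blueFrames[[j]] else .stackBlue(stack, i)
    comp <- cpp_components(blue, threshold, as.integer(cfg@connectivity),
                           as.integer(cfg@minAreaPx))$stats
    if (!nrow(comp)) next
    comp$frame <- i
    comp$x_um <- fo$x0_um[i] + (comp$cx - 0.5) * px
    comp$y_um <- fo$y0_um[i] + (comp$cy - 0.5) * px
    out[[j]] <- comp
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(label = integer(), area_px = numeric(), cx = numeric(),
                      cy = numeric(), mu_xx = numeric(), mu_yy = numeric(),
                      mu_xy = numeric(), mean_intensity = numeric(),
                      row_min = integer(), row_max = integer(),
                      col_min = integer(), col_max = integer(),
                      frame = integer(), x_um = numeric(), y_um = numeric()))
  do.call(rbind, out)
}

#' Refine one detection inside its crop
#'
#' Re-segments a crop centred on a first-pass detection with a local
#' threshold (crop mean - c x crop SD, floored at the global threshold minus
#' the guard band), keeps the component containing the crop centre, and
#' requires it to overlap the first-pass mask by at least \code{overlapMin}.
#'
#' @param crop Single-channel integer matrix centred on the detection.
#' @param cfg A SegmentationConfig.
#' @param globalThreshold The stack/global threshold used in the first pass.
#' @param center c(row, col) of the detection centre within the crop.
#' @param pixelSize um per pixel (for the refined area).
#' @param firstMask Optional logical matrix (same size as crop) of the
#'   first-pass component's pixels.
#' @return list(ok, area_px, area_um2, elongation, mean_intensity, cy, cx).
#'   \code{ok = FALSE} flags a detection lost at the local threshold.
#' @export
refineParticle <- function(crop, cfg = segmentationConfig(), globalThreshold,
                           center = (dim(crop) + 1) / 2, pixelSize = 1,
                           firstMask = NULL) {
  localThr <- mean(crop) - cfg@localThresholdC * stats::sd(crop)
  localThr <- max(localThr, globalThreshold - cfg@guardBand)
  res <- cpp_components(crop, localThr, as.integer(cfg@connectivity), 1L)
  lab <- res$labels
  fail <- list(ok = FALSE, area_px = NA_real_, area_um2 = NA_real_,
               elongation = NA_real_, mean_intensity = NA_real_,
               cy = center[1], cx = center[2])
  if (!nrow(res$stats)) return(fail)
  r0 <- max(1L, min(nrow(lab), round(center[1])))
  c0 <- max(1L, min(ncol(lab), round(center[2])))
  k <- lab[r0, c0]
  if (k == 0L) {  # centre pixel not dark at the local threshold: use the
    # component nearest to the centre within 2 px, if any
    d <- sqrt((res$stats$cy - center[1])^2 + (res$stats$cx - center[2])^2)
    near <- which(d <= max(2, sqrt(res$stats$area_px / pi)))
    if (!length(near)) return(fail)
    k <- res$stats$label[near[which.min(d[near])]]
  }
  if (!is.null(firstMask)) {
    inter <- sum(lab == k & firstMask)
    if (inter / sum(firstMask) < cfg@overlapMin) return(fail)
  }
  s <- res$stats[res$stats$label == k, ]
  list(ok = TRUE, area_px = s$area_px, area_um2 = s$area_px * pixelSize^2,
       elongation = .elongation(s$mu_xx, s$mu_yy, s$mu_xy),
       mean_intensity = s$mean_intensity, cy = s$cy, cx = s$cx)
}

#' Run the complete segmentation for one stack
#'
#' Orchestrates the published two-pass procedure: channel extraction, then at
#' high zoom shadow-frame rejection followed by the stack threshold (the
#' median + k x mean-SD statistic applied on the darkness scale, i.e. a grey
#' threshold of median - k x mean SD), or the constant grey threshold at low
#' zoom; first-pass connected components; and per-detection crop refinement
#' (blue component at low zoom, 8-bit grey average at high zoom). Purely
#' deterministic for a fixed input stack.
#'
#' @param stack A FrameStack.
#' @param cfg A SegmentationConfig.
#' @param refine Refine detections (default TRUE; the low-zoom pass is also
#'   refined when \code{cfg@refineLowZoom} is TRUE).
#' @return Detection data.frame with columns frame, x_um, y_um, area_px,
#'   area_um2 (refined where available), elongation, mean_intensity,
#'   refined, retained; attribute \code{log} records thresholds, rejected
#'   frames and per-stage counts, attribute \code{pixelSize} the calibration.
#' @export
runSegmentation <- function(stack, cfg = segmentationConfig(), refine = TRUE) {
  zoom <- zoomLevel(stack)
  n <- nFrames(stack)
  maxval <- 255
  doRefine <- refine && (zoom == "high" || cfg@refineLowZoom)

  if (zoom == "high") {
    # pass A: per-frame histograms of the blue channel (frames re-rendered
    # lazily), provisional rejection, then the final stack threshold over
    # retained frames only
    hists <- vector("list", n)
    for (i in seq_len(n))
      hists[[i]] <- .frameHist(.stackBlue(stack, i))
    rej <- .rejectFromHists(hists, cfg, maxval)
    retained <- rej$retained
    if (!length(retained)) {
      warning("all frames rejected as shadowed; empty detection table")
      det <- firstPassSegment(stack, -1, cfg, integer())
      det$refined <- logical(0); det$retained <- logical(0)
      attr(det, "log") <- list(zoom = zoom, threshold = NA_real_,
                               rejectedFrames = rej$rejected,
                               nFrames = n, nDetections = 0L)
      return(det)
    }
    thrD <- computeStackThreshold(NULL, cfg@highZoomK,
                                  hists = lapply(hists[retained], rev))
    threshold <- maxval - thrD
    rejected <- rej$rejected
  } else {
    threshold <- cfg@lowZoomThreshold
    retained <- seq_len(n)
    rejected <- integer()
  }

  px <- pixelSize(stack)
  fo <- frameOrigins(stack)
  rows <- vector("list", length(retained))
  generated <- length(stack@generator) > 0
  for (j in seq_along(retained)) {
    i <- retained[j]
    blue <- .stackBlue(stack, i)
    seg <- cpp_components(blue, threshold, as.integer(cfg@connectivity),
                          as.integer(cfg@minAreaPx))
    comp <- seg$stats
    if (!nrow(comp)) next
    comp$frame <- i
    comp$refined <- FALSE
    comp$retained <- TRUE
    comp$area_um2 <- comp$area_px * px^2
    comp$elongation <- .elongation(comp$mu_xx, comp$mu_yy, comp$mu_xy)
    if (doRefine) {
      # refinement samples the grey average at high zoom; for generated
      # stacks it is derived from the blue scene per crop, identically to
      # the materialised RGB average
      ref <- if (zoom != "high") blue
      else if (generated) NULL
      else .grayChannel(getFrame(stack, i), bitDepth(stack))
      for (d in seq_len(nrow(comp))) {
        hw <- ceiling(2 * sqrt(comp$area_px[d] / pi) + cfg@cropMarginPx)
        r <- round(comp$cy[d]); c <- round(comp$cx[d])
        rr <- max(1, r - hw):min(nrow(blue), r + hw)
        cc <- max(1, c - hw):min(ncol(blue), c + hw)
        crop <- if (is.null(ref)) .grayFromBlue(blue[rr, cc, drop = FALSE])
        else ref[rr, cc, drop = FALSE]
        firstMask <- seg$labels[rr, cc, drop = FALSE] == comp$label[d]
        out <- refineParticle(crop, cfg, threshold,
                              center = c(comp$cy[d] - rr[1] + 1,
                                         comp$cx[d] - cc[1] + 1),
                              pixelSize = px, firstMask = firstMask)
        if (out$ok) {
          comp$refined[d] <- TRUE
          comp$area_px[d] <- out$area_px
          comp$area_um2[d] <- out$area_um2
          comp$elongation[d] <- out$elongation
          comp$mean_intensity[d] <- out$mean_intensity
          comp$cy[d] <- out$cy + rr[1] - 1
          comp$cx[d] <- out$cx + cc[1] - 1
        } else {
          comp$retained[d] <- FALSE  # flagged, not silently dropped
        }
      }
    }
    comp$x_um <- fo$x0_um[i] + (comp$cx - 0.5) * px
    comp$y_um <- fo$y0_um[i] + (comp$cy - 0.5) * px
    rows[[j]] <- comp
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  det <- if (length(rows)) do.call(rbind, rows) else {
    d0 <- firstPassSegment(stack, -1, cfg, integer())
    d0$refined <- logical(0); d0$retained <- logical(0); d0
  }
  rownames(det) <- NULL
  attr(det, "log") <- list(zoom = zoom, threshold = threshold,
                           rejectedFrames = rejected, nFrames = n,
                           nRetainedFrames = length(retained),
                           nDetections = nrow(det),
                           nRefined = sum(det$refined))
  attr(det, "pixelSize") <- px
  attr(det, "retainedFrames") <- retained
  det
}

#' Match detections against ground truth
#'
#' One-to-one greedy nearest-neighbour matching within a radius: candidate
#' pairs are processed in order of increasing distance; unmatched ground
#' truth counts as a miss, unmatched detections as false positives.
#'
#' @param truth Ground-truth table (x_um, y_um, area_um2).
#' @param det Detection table (x_um, y_um, area_um2); only rows with
#'   \code{retained} TRUE are used if the column is present.
#' @param radius Matching radius, um.
#' @return list(precision, recall, nTruth, nDetections, matches) where
#'   matches holds per-pair distances and relative area errors.
#' @export
matchDetections <- function(truth, det, radius) {
  if (radius <= 0) stop("radius must be > 0")
  if (!is.null(det$retained)) det <- det[det$retained, , drop = FALSE]
  nT <- nrow(truth); nD <- nrow(det)
  empty <- data.frame(truthIdx = integer(), detIdx = integer(),
                      dist_um = numeric(), areaError = numeric())
  if (!nT || !nD) {
    return(list(precision = if (nD) 0 else NA_real_,
                recall = if (nT) 0 else NA_real_,
                nTruth = nT, nDetections = nD, matches = empty))
  }
  dx <- outer(truth$x_um, det$x_um, "-")
  dy <- outer(truth$y_um, det$y_um, "-")
  dist <- sqrt(dx * dx + dy * dy)
  cand <- which(dist < radius, arr.ind = TRUE)  # strictly within the radius
  matches <- empty
  if (nrow(cand)) {
    ord <- order(dist[cand])
    cand <- cand[ord, , drop = FALSE]
    usedT <- logical(nT); usedD <- logical(nD)
    for (r in seq_len(nrow(cand))) {
      ti <- cand[r, 1]; di <- cand[r, 2]
      if (usedT[ti] || usedD[di]) next
      usedT[ti] <- TRUE; usedD[di] <- TRUE
      matches <- rbind(matches, data.frame(
        truthIdx = ti, detIdx = di, dist_um = dist[ti, di],
        areaError = (det$area_um2[di] - truth$area_um2[ti]) /
          truth$area_um2[ti]))
    }
  }
  list(precision = nrow(matches) / nD, recall = nrow(matches) / nT,
       nTruth = nT, nDetections = nD, matches = matches)
}
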