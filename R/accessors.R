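#' Accessors for ParticleScan objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x A ParticleScan S4 object.
#' @param i Frame index (for \code{getFrame}).
#' @return The corresponding slot value (or materialised frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("zoomLevel", function(x) standardGeneric("zoomLevel"))
#' @rdname accessors
#' @export
setMethod("zoomLevel", "FrameStack", function(x) x@zoom)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) nrow(x@frameOrigins))

#' @rdname accessors
#' @export
setGeneric("frameOrigins", function(x) standardGeneric("frameOrigins"))
#' @rdname accessors
#' @export
setMethod("frameOrigins", "FrameStack", function(x) x@frameOrigins)

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setMethod("bitDepth", "FrameStack", function(x) x@bitDepth)

#' Materialise one frame of a stack
#'
#' For eager stacks this returns the stored array; for lazy stacks the frame
#' is re-rendered deterministically from the stored generator spec and the
#' per-frame seed, so repeated access is bit-identical.
#'
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setMethod("getFrame", "FrameStack", function(x, i) {
  if (length(x@frames) >= i && !is.null(x@frames[[i]])) return(x@frames[[i]])
  if (!length(x@generator)) stop("frame ", i, " is not materialised")
  renderFrame(x@generator$truth, x@generator$config, x@zoom, x, i,
              x@generator$frameSeeds[i])
})

#' Imaged area of a stack in mm^2, optionally for a subset of frames
#'
#' @param x A FrameStack.
#' @param frames Frame indices to include (default all).
#' @return Area covered by the selected frame footprints, mm^2.
#' @export
imagedArea <- function(x, frames = seq_len(nFrames(x))) {
  px <- prod(x@frameDim) * length(frames)
  px * x@pixelSize^2 / 1e6
}

#' Bounding box of the imaged strip in window coordinates (um)
#'
#' @param x A FrameStack.
#' @return Named numeric c(x0, x1, y0, y1).
#' @export
imagedBounds <- function(x) {
  fo <- x@frameOrigins
  w <- x@frameDim[2] * x@pixelSize
  h <- x@frameDim[1] * x@pixelSize
  c(x0 = min(fo$x0_um), x1 = max(fo$x0_um) + w,
    y0 = min(fo$y0_um), y1 = max(fo$y0_um) + h)
}

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setMethod("particles", "WindowResult", function(x) x@particles)

#' @rdname accessors
#' @export
setGeneric("windowArea", function(x) standardGeneric("windowArea"))
#' @rdname accessors
#' @export
setMethod("windowArea", "WindowResult", function(x) x@imagedAreaMm2)

#' Midpoint of the maximal histogram bin
#'
#' @param x A SizeDistribution.
#' @return Midpoint (um^2) of the bin with the largest count.
#' @export
modeBin <- function(x) {
  stopifnot(is(x, "SizeDistribution"))
  if (!sum(x@counts)) return(NA_real_)
  i <- which.max(x@counts)
  (x@binEdges[i] + x@binEdges[i + 1]) / 2
}

#' @rdname accessors
#' @export
setGeneric("asymmetryIndex", function(x) standardGeneric("asymmetryIndex"))
#' @rdname accessors
#' @export
setMethod("asymmetryIndex", "SpatialProfile", function(x) x@asymmetryIndex)

#' @rdname accessors
#' @export
setGeneric("kineticSlope", function(x) standardGeneric("kineticSlope"))
#' @rdname accessors
#' @export
setMethod("kineticSlope", "KineticsFit", function(x) x@slope)
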