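# Shared fixtures: tiny campaigns and hand-built stacks, all generated in
# code at test time.

# a small campaign whose strips render in well under a second
tinyCampaign <- function(coarse = 2, fine = 4, macro = 0, gradient = "none",
                         sCoarse = 0, sFine = 0, noise = 5) {
  im <- imagingPreset("desk")
  im$stripWidthLowUm <- 1000
  im$stripWidthHighUm <- 120
  im$gridLow <- c(1L, 2L)
  im$gridHigh <- c(1L, 4L)
  campaignConfig(name = "tiny", coarseDensity = coarse, fineDensity = fine,
                 macroRate = macro,
                 gradient = list(type = gradient, strengthCoarse = sCoarse,
                                 strengthFine = sFine),
                 noiseSd = noise, imaging = im)
}

# one-particle ground-truth row in window coordinates
truthRow <- function(x, y, area, shape = "coccus", class = "coarse",
                     angle = 0, aspect = 8, shapeSeed = 1) {
  data.frame(id = 1L, x_um = x, y_um = y, nominal_um2 = area,
             area_um2 = area, shape = shape, class = class, angle = angle,
             aspect = aspect, shapeSeed = shapeSeed)
}

emptyTruth <- function() truthRow(1, 1, 1)[0, ]

# hand-built FrameStack around explicit integer RGB arrays
manualStack <- function(frames, zoom = "low", pixelSize = 1,
                        origins = NULL, bitDepth = 8, windowUm = 8000) {
  d <- dim(frames[[1]])
  if (is.null(origins))
    origins <- data.frame(frame = seq_along(frames),
                          x0_um = 0,
                          y0_um = (seq_along(frames) - 1) * d[1] * pixelSize)
  new("FrameStack", frames = frames, zoom = zoom, pixelSize = pixelSize,
      frameDim = as.integer(d[1:2]), frameOrigins = origins,
      bitDepth = bitDepth, windowUm = windowUm, generator = list(),
      metadata = list())
}

# constant-background RGB frame with optional rectangular dark patches
flatFrame <- function(nr, nc, rgb = c(218, 208, 200)) {
  array(rep(as.integer(rgb), each = nr * nc), dim = c(nr, nc, 3L))
}

# stamp a dark axis-aligned rectangle into all three channels
darkenRect <- function(frame, rows, cols, level) {
  for (ch in 1:3) frame[rows, cols, ch] <- as.integer(level)
  frame
}

# truth filtered to particles whose centre lies in the imaged strip of a
# stack (with a small margin so edge-clipped particles are not counted)
truthInStrip <- function(truth, stack, class = NULL, margin = 3) {
  b <- imagedBounds(stack)
  keep <- truth$x_um >= b["x0"] + margin & truth$x_um < b["x1"] - margin
  if (!is.null(class)) keep <- keep & truth$class == class
  truth[keep, , drop = FALSE]
}
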