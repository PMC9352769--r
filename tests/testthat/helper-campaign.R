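# Closed-loop campaign runner shared by the acceptance-style tests: simulate
# replicate windows under a packaged reference config and return per-window
# densities for one class, at a desk-scale imaging geometry.

runCampaign <- function(campaign, days, zoom, nWindows, seed,
                        stripUm = NULL, gridLow = NULL, pixelHigh = NULL,
                        what = c("density", "windows")) {
  what <- match.arg(what)
  im <- imagingPreset("desk")
  if (!is.null(pixelHigh)) im$pixelSizeHigh <- pixelHigh
  if (!is.null(stripUm)) {
    if (zoom == "low") im$stripWidthLowUm <- stripUm
    else im$stripWidthHighUm <- stripUm
  }
  if (!is.null(gridLow)) im$gridLow <- gridLow
  cfg <- referenceConfig(campaign, days, imaging = im)
  set.seed(seed)
  windows <- lapply(seq_len(nWindows), function(w) {
    sim <- simulateWindow(cfg, zoom, lazy = TRUE)
    analyzeStack(sim$stack, windowId = sprintf("w%02d", w))
  })
  if (what == "windows") return(windows)
  list(fine = densitySummary(windows, "fine"),
       coarse = densitySummary(windows, "coarse"),
       windows = windows)
}
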