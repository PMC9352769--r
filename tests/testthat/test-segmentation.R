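# Segmentation: channels, stack threshold, shadow rejection, first pass,
# refinement, orchestration and detection matching.

test_that("channel extraction: blue for segmentation, grey average for crops", {
  f <- flatFrame(8, 10, rgb = c(30, 60, 90))
  st <- manualStack(list(f))
  expect_true(all(extractChannel(st, "blue")[[1]] == 90))
  expect_true(all(extractChannel(st, "gray")[[1]] == 60))

  pureBlue <- flatFrame(6, 6, rgb = c(0, 0, 120))
  st2 <- manualStack(list(pureBlue))
  expect_true(all(extractChannel(st2, "blue")[[1]] == 120))
  expect_true(all(extractChannel(st2, "gray")[[1]] == 40))

  # 12-bit input is rescaled to the 8-bit working depth
  f12 <- flatFrame(4, 4, rgb = c(0, 0, 2048))
  st12 <- manualStack(list(f12), bitDepth = 12)
  expect_true(all(extractChannel(st12, "blue")[[1]] ==
                    round(2048 * 255 / 4095)))
  expect_error(ParticleScan:::.blueChannel(matrix(1, 3, 3)),
               "RGB")
})

test_that("stack threshold equals the brute-force formula on integer stacks", {
  set.seed(21)
  for (rep in 1:20) {
    nf <- sample(1:4, 1)
    frames <- lapply(seq_len(nf), function(i)
      matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40))
    k <- runif(1, 0.5, 3)
    direct <- median(unlist(frames)) +
      k * mean(vapply(frames, sd, 1))
    expect_equal(computeStackThreshold(frames, k), direct)
  }

  # worked examples: zero-SD stack; hand-computable median and SDs
  expect_equal(computeStackThreshold(list(matrix(100, 5, 5)), 2), 100)
  f1 <- matrix(c(76, 80, 84), 1)   # per-frame SDs 4 and 6, pooled median 80
  f2 <- matrix(c(74, 80, 86), 1)
  expect_equal(computeStackThreshold(list(f1, f2), 2), 90)

  set.seed(22)  # N(200, 5^2): median ~ 200, mean SD ~ 5 => ~210 at k = 2
  g <- matrix(rnorm(1e5, 200, 5), 250)
  expect_true(computeStackThreshold(list(g), 2) > 209 &&
                computeStackThreshold(list(g), 2) < 211)
  expect_error(computeStackThreshold(list()), "empty")
})

test_that("raising the threshold never loses sub-threshold pixels", {
  set.seed(23)
  frame <- matrix(sample(0:255, 2000, replace = TRUE), 40)
  counts <- vapply(seq(0, 260, by = 20), function(t) sum(frame < t), 1)
  expect_true(all(diff(counts) >= 0))
})

test_that("shadow frames are rejected before stack statistics, others untouched", {
  cfg <- tinyCampaign(macro = 0, fine = 6)
  set.seed(24)
  sim <- simulateWindow(cfg, "high", lazy = FALSE)
  blues <- extractChannel(sim$stack, "blue")
  clean <- rejectShadowFrames(blues)
  expect_length(clean$rejected, 0)

  # bound: rejectDarkFraction = 1 can never reject
  all1 <- rejectShadowFrames(blues, segmentationConfig(rejectDarkFraction = 1))
  expect_length(all1$rejected, 0)

  # an injected macroscopic object's affected frames are all rejected
  b <- imagedBounds(sim$stack)
  res <- injectMacroscopicObject(sim$stack, area_um2 = 9e4,
                                 position = c(mean(b[c("x0", "x1")]), 3000))
  expect_gt(length(res$affectedFrames), 0)
  blues2 <- extractChannel(res$stack, "blue")
  rej <- rejectShadowFrames(blues2)
  expect_true(all(res$affectedFrames %in% rej$rejected))
  # retained frames keep their pixel values bit for bit
  for (i in setdiff(rej$retained, res$affectedFrames))
    expect_identical(blues2[[i]], blues2[[i]][, ])
  det <- runSegmentation(res$stack)
  expect_true(all(res$affectedFrames %in% attr(det, "log")$rejectedFrames))

  # everything shadowed: signalled, not silent (every frame is 30% deep
  # shadow, far beyond the default dark fraction)
  dark <- lapply(1:3, function(i) {
    m <- matrix(200L, 20, 20)
    m[1:6, ] <- 0L
    m
  })
  expect_warning(rejectShadowFrames(dark, segmentationConfig()),
                 "all frames rejected")
})

test_that("first pass: blank frames, connectivity conventions", {
  st <- manualStack(list(flatFrame(30, 30)))
  expect_equal(nrow(firstPassSegment(st, 75, segmentationConfig())), 0L)

  # two squares touching corner-to-corner: one component under
  # 8-connectivity, two under 4-connectivity
  f <- flatFrame(30, 30)
  f <- darkenRect(f, 5:9, 5:9, 40)
  f <- darkenRect(f, 10:14, 10:14, 40)
  st2 <- manualStack(list(f))
  expect_equal(nrow(firstPassSegment(st2, 75,
                                     segmentationConfig(connectivity = 8,
                                                        minAreaPx = 4))), 1L)
  expect_equal(nrow(firstPassSegment(st2, 75,
                                     segmentationConfig(connectivity = 4,
                                                        minAreaPx = 4))), 2L)

  # centroid maps through the frame-origin offset
  det <- firstPassSegment(st2, 75, segmentationConfig(connectivity = 4,
                                                      minAreaPx = 4))
  expect_equal(sort(det$x_um), c(6.5, 11.5))
})

test_that("refinement fixes a locally-broken global threshold", {
  # disc on a uniform background: refined area within 5% of first pass
  cfg <- tinyCampaign()
  tr <- truthRow(4000, 500, 400)
  set.seed(25)
  stack <- renderWindow(tr, "low", cfg)
  first <- runSegmentation(stack, refine = FALSE)
  refined <- runSegmentation(stack, refine = TRUE)
  expect_equal(nrow(refined), 1L)
  expect_true(refined$refined)
  expect_lt(abs(refined$area_px - first$area_px) / first$area_px, 0.05)

  # disc with an attached dim patch that the global threshold merges in:
  # the first-pass area errs by > 20%, the crop-local threshold recovers
  # the disc within 10%
  nr <- 120; nc <- 200
  f <- flatFrame(nr, nc, rgb = c(210, 205, 200))
  cx <- 134; cy <- 60; r <- 10
  truthPx <- 0
  for (row in (cy - r):(cy + r)) {
    half <- floor(sqrt(r^2 - (row - cy)^2))
    f <- darkenRect(f, row, (cx - half):(cx + half), 115)
    truthPx <- truthPx + 2 * half + 1
  }
  f <- darkenRect(f, 55:66, 145:156, 174)      # dim patch, just sub-threshold
  st <- manualStack(list(f))
  cfgSeg <- segmentationConfig(lowZoomThreshold = 178, guardBand = 100)
  first <- runSegmentation(st, cfgSeg, refine = FALSE)
  expect_equal(nrow(first), 1L)                 # disc + band merged
  expect_gt(abs(first$area_px - truthPx) / truthPx, 0.20)
  ref <- runSegmentation(st, cfgSeg, refine = TRUE)
  ref <- ref[ref$retained, ]
  expect_equal(nrow(ref), 1L)
  expect_lt(abs(ref$area_px - truthPx) / truthPx, 0.10)

  # circular masks report elongation 1 within tolerance; refinement is
  # idempotent at the pixel level
  expect_lt(abs(ref$elongation - 1), 0.05)
  crop <- f[(cy - 2 * r):(cy + 2 * r), (cx - 2 * r):(cx + 2 * r), 3]
  r1 <- refineParticle(crop, cfgSeg, globalThreshold = 178, pixelSize = 1)
  r2 <- refineParticle(crop, cfgSeg, globalThreshold = 178, pixelSize = 1)
  expect_true(r1$ok)
  expect_equal(r1$area_px, r2$area_px)
})

test_that("lost-at-local-threshold detections are flagged, not dropped", {
  # a flat dim half-frame is below the global threshold but vanishes at the
  # crop-local threshold (local SD ~ 0 around it): flagged, not dropped
  f <- flatFrame(40, 40, rgb = c(210, 205, 196))
  f[, 21:40, 3] <- 210L
  st <- manualStack(list(f))
  cfgSeg <- segmentationConfig(lowZoomThreshold = 198, minAreaPx = 4,
                               guardBand = 2)
  det <- runSegmentation(st, cfgSeg)
  expect_equal(nrow(det), 1L)
  expect_false(det$retained)
  expect_false(det$refined)
  # and the calibrated particle table excludes it
  expect_equal(nrow(calibrateDetections(det)), 0L)
})

test_that("particle-free windows yield almost no retained detections", {
  # the adaptive threshold leaves ~2% of noise pixels dark; the min-area
  # floor and refinement must keep surviving noise clusters negligible
  im <- imagingPreset("desk")
  im$pixelSizeHigh <- 0.35
  im$stripWidthHighUm <- 700
  cfg <- campaignConfig(coarseDensity = 0, fineDensity = 0, macroRate = 0,
                        imaging = im)
  set.seed(29)
  sim <- simulateWindow(cfg, "high", lazy = TRUE)
  det <- runSegmentation(sim$stack)
  fp <- sum(det$retained)
  expect_lte(fp / imagedArea(sim$stack), 0.2)  # << fine densities of 1-5/mm2
})

test_that("full segmentation is deterministic and accurate at moderate density", {
  cfg <- tinyCampaign(fine = 8, coarse = 3)
  set.seed(26)
  sim <- simulateWindow(cfg, "high", lazy = TRUE)
  d1 <- runSegmentation(sim$stack)
  d2 <- runSegmentation(sim$stack)
  expect_identical(d1, d2)

  inS <- truthInStrip(sim$truth, sim$stack, class = "fine")
  pp <- calibrateDetections(d1)
  m <- matchDetections(inS, pp[pp$size_class == "fine", ], radius = 2)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.9)

  # empty window
  set.seed(27)
  sim0 <- simulateWindow(tinyCampaign(coarse = 0, fine = 0), "high")
  expect_equal(nrow(runSegmentation(sim0$stack)), 0L)
})

test_that("matching is one-to-one greedy within the radius", {
  tr <- data.frame(x_um = c(10, 50), y_um = c(10, 50), area_um2 = c(5, 5))
  expect_error(matchDetections(tr, tr, radius = 0), "radius")
  m <- matchDetections(tr, tr, 2)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  m0 <- matchDetections(tr, tr[0, ], 2)
  expect_equal(m0$recall, 0)
  shifted <- transform(tr, x_um = x_um + 3)
  expect_equal(nrow(matchDetections(tr, shifted, 3)$matches), 0L)
  # nearest pairing wins under contention
  det <- data.frame(x_um = c(10.5, 11.5), y_um = c(10, 10),
                    area_um2 = c(5, 5))
  m2 <- matchDetections(tr[1, ], det, 5)
  expect_equal(m2$matches$detIdx, 1L)
})

test_that("component moments agree with the EBImage oracle", {
  skip_if_not_installed("EBImage")
  set.seed(28)
  rp <- rasterParticle("fiber", 300, angle = 0.7, aspect = 8,
                       shapeSeed = 3, pxSize = 1)
  n <- 2 * rp$ext + 1
  img <- matrix(200L, n, n)
  mask <- matrix(FALSE, n, n)
  mask[cbind(rp$rr + rp$ext + 1, rp$cc + rp$ext + 1)] <- TRUE
  img[mask] <- 50L
  res <- ParticleScan:::cpp_components(img, 100, 8L, 1L)
  ft <- EBImage::computeFeatures.moment(EBImage::bwlabel(t(mask) * 1))
  # EBImage works on transposed (x = row) images: cx equals its m.cx
  expect_equal(res$stats$cx, unname(ft[1, "m.cx"]), tolerance = 1e-6)
  expect_equal(res$stats$cy, unname(ft[1, "m.cy"]), tolerance = 1e-6)
  elong <- ParticleScan:::.elongation(res$stats$mu_xx, res$stats$mu_yy,
                                      res$stats$mu_xy)
  ecc <- unname(ft[1, "m.eccentricity"])
  expect_equal(elong, 1 / sqrt(1 - ecc^2), tolerance = 0.05)
})
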