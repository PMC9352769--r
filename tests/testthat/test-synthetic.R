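# Generator: configs, Poisson counts, placement, rendering, macro objects.

test_that("campaign config validity catches bad parameters", {
  expect_error(campaignConfig(occupancyRate = 1.2), "occupancyRate")
  expect_error(campaignConfig(coarseDensity = -1), "densities")
  expect_error(campaignConfig(shapeMixFine = c(coccus = 0.5, fiber = 0.2)),
               "sum to 1")
  expect_error(campaignConfig(gradient = list(type = "quadratic",
                                              strengthCoarse = 1,
                                              strengthFine = 1)),
               "gradient")
  expect_s4_class(campaignConfig(), "CampaignConfig")
})

test_that("particle counts are Poisson with mean density x area", {
  cfg0 <- tinyCampaign(coarse = 0)
  set.seed(1)
  expect_true(all(replicate(50, drawParticleCount(cfg0, "coarse", 64)) == 0))
  expect_error(drawParticleCount(tinyCampaign(), "giant", 64), "size class")

  # closed form: mean 2.0/mm2 x 64 mm2 = 128, SE = sqrt(128 / 1e4)
  cfg <- tinyCampaign(coarse = 2)
  set.seed(2)
  cnt <- replicate(1e4, drawParticleCount(cfg, "coarse", 64))
  expect_lt(abs(mean(cnt) - 128), 3 * sqrt(128 / 1e4))
  expect_lt(abs(var(cnt) - 128), 5 * sqrt(2 * 128^2 / 1e4))

  # printed long-duration density: 0.36/mm2 over the 8 x 8 mm window
  cfg25 <- referenceConfig("MATISS-2.5", 365)
  set.seed(3)
  cnt <- replicate(1e4, drawParticleCount(cfg25, "coarse", 64))
  expect_lt(abs(mean(cnt) - 23.04), 3 * sqrt(23.04 / 1e4))
})

test_that("placement is inside the window and uniform without gradient", {
  cfg <- tinyCampaign()
  set.seed(4)
  tr <- placeParticles(cfg, 4000, "coarse")
  W <- cfg@imaging$windowUm
  expect_true(all(tr$x_um >= 0 & tr$x_um < W))
  expect_true(all(tr$y_um >= 0 & tr$y_um < W))
  expect_gt(stats::ks.test(tr$y_um / W, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(tr$x_um / W, "punif")$p.value, 0.01)
  expect_error(placeParticles(cfg, -1), "count")
  expect_equal(nrow(placeParticles(cfg, 0)), 0)
})

test_that("gradient placement is monotone along y and recovers strength", {
  # coarse towards the aperture (y = 0): decreasing counts; fine away:
  # increasing counts (the mirrored case)
  cfg <- tinyCampaign(gradient = "exponential", sCoarse = 1.5, sFine = -1.5)
  H <- cfg@imaging$windowUm
  set.seed(5)
  yc <- placeParticles(cfg, 6000, "coarse")$y_um
  yf <- placeParticles(cfg, 6000, "fine")$y_um
  hc <- table(cut(yc, seq(0, H, length.out = 5)))
  hf <- table(cut(yf, seq(0, H, length.out = 5)))
  expect_true(all(diff(as.numeric(hc)) < 0))
  expect_true(all(diff(as.numeric(hf)) > 0))

  # MLE of the exponential strength on ground truth recovers the seeded
  # value within 3 SE (independent fit, not the sampler's inverse CDF)
  nll <- function(s, y) {
    if (abs(s) < 1e-9) return(0)
    -sum(log(s / H) - s * y / H - log(1 - exp(-s)))
  }
  fit <- stats::optim(1, nll, y = yc, method = "BFGS", hessian = TRUE)
  se <- sqrt(1 / fit$hessian[1, 1])
  expect_lt(abs(fit$par - 1.5), 3 * se)
})

test_that("empty truth renders pure background and no detections", {
  cfg <- tinyCampaign(noise = 5)
  set.seed(6)
  stack <- renderWindow(emptyTruth(), "low", cfg)
  f <- getFrame(stack, 1)
  blue <- f[, , 3]
  expect_lt(abs(mean(blue) - 200), 0.5)
  expect_lt(abs(sd(blue) - 5), 0.3)
  det <- runSegmentation(stack, segmentationConfig())
  expect_equal(nrow(det), 0L)
})

test_that("a 155 um^2 disc renders as one dark region of matching area", {
  cfg <- tinyCampaign()
  b <- c(x0 = 3500, y0 = 0)  # strip is centred: 1000 um wide at low zoom
  tr <- truthRow(4000, 1000, 155)
  set.seed(7)
  stack <- renderWindow(tr, "low", cfg)
  px <- pixelSize(stack)
  det <- runSegmentation(stack, segmentationConfig(), refine = FALSE)
  expect_equal(nrow(det), 1L)
  expect_lte(abs(det$area_px * px^2 - 155) / 155, 0.05)
  expect_lt(abs(det$x_um - 4000), px)
  expect_lt(abs(det$y_um - 1000), px)
})

test_that("rendering is deterministic in truth and varies only with noise", {
  cfg <- tinyCampaign()
  set.seed(8)
  tr <- placeParticles(cfg, 10, "coarse")
  set.seed(100)
  s1 <- renderWindow(tr, "low", cfg)
  set.seed(100)
  s2 <- renderWindow(tr, "low", cfg)
  expect_identical(getFrame(s1, 1), getFrame(s2, 1))  # seed contract
  set.seed(101)
  s3 <- renderWindow(tr, "low", cfg)
  expect_identical(groundTruth(s1)$area_um2, groundTruth(s3)$area_um2)
  expect_false(identical(getFrame(s1, 1), getFrame(s3, 1)))
  # lazy re-rendering is bit-identical to eager rendering
  set.seed(100)
  s4 <- renderWindow(tr, "low", cfg, lazy = TRUE)
  expect_identical(getFrame(s4, 2), getFrame(s1, 2))
})

test_that("rendered pixel areas match nominal within 5% from 20 px up", {
  shapes <- c("coccus", "dividing_coccus_with_halo", "hexagonal_disc",
              "fiber", "angular_crystal", "parallelepiped_aggregate")
  for (shape in shapes) {
    for (targetPx in c(20, 60, 300, 2000)) {
      for (k in 1:3) {
        rp <- rasterParticle(shape, targetPx, angle = k, aspect = 8,
                             shapeSeed = 11 * k, pxSize = 1)
        expect_lte(abs(rp$areaPx - targetPx) / targetPx, 0.05,
                  label = paste(shape, targetPx, k))
      }
    }
  }
})

test_that("ground truth conserves class counts and rendered-area bookkeeping", {
  cfg <- tinyCampaign(coarse = 5, fine = 10)
  set.seed(9)
  sim <- simulateWindow(cfg, "low", lazy = TRUE)
  expect_equal(sum(table(sim$truth$class)), nrow(sim$truth))
  # rendered area equals the rasterised pixel count exactly for particles
  # near the imaged strip (one-pixel consistency by construction)
  inS <- truthInStrip(sim$truth, sim$stack)
  px <- pixelSize(sim$stack)
  expect_true(all(abs(inS$area_um2 / px^2 -
                        round(inS$area_um2 / px^2)) < 1e-9))
})

test_that("macroscopic objects: bookkeeping, class and affected frames", {
  cfg <- tinyCampaign(macro = 0)
  set.seed(10)
  sim <- simulateWindow(cfg, "high", lazy = TRUE)
  expect_length(sim$affectedFrames, 0)        # macro rate 0: nothing
  expect_null(sim$stack@generator$macros)

  stack <- sim$stack
  res <- injectMacroscopicObject(stack, area_um2 = 2000)
  expect_equal(groundTruth(res$stack)$class[nrow(groundTruth(res$stack))],
               "macroscopic")                 # > 1500 um^2 => macroscopic
  expect_error(injectMacroscopicObject(stack, area_um2 = 1000), "1500")

  # a large object placed mid-strip must report affected frames consistent
  # with the frame-origin map
  b <- imagedBounds(stack)
  res2 <- injectMacroscopicObject(stack, area_um2 = 8e4,
                                  position = c(mean(b[c("x0", "x1")]), 4000))
  expect_gt(length(res2$affectedFrames), 0)
  fo <- frameOrigins(res2$stack)
  h <- res2$stack@frameDim[1] * pixelSize(res2$stack)
  centres <- fo$y0_um + h / 2
  rSh <- 3 * sqrt(8e4 / pi)
  expect_true(all(abs(centres[res2$affectedFrames] - 4000) < rSh + h))
})

test_that("reference configs carry the printed campaign values", {
  c1 <- referenceConfig("MATISS-1", 193)
  expect_equal(c1@coarseDensity, 2.45)
  expect_equal(c1@fineDensity, 4.45)
  expect_equal(c1@exposureDays, 193)
  c2 <- referenceConfig("MATISS-2", 95)
  expect_equal(c2@fineDensity, 3.82)
  c3 <- referenceConfig("MATISS-2.5", 365)
  expect_equal(c3@coarseDensity, 0.36)
  expect_equal(c3@occupancyRate, 0.35)
  expect_error(referenceConfig("MATISS-3", 10), "no packaged reference")
  # intermediate MATISS-2 fine densities are collinear with the printed pair
  tab <- referenceCampaigns()
  m2 <- tab[tab$campaign == "MATISS-2", ]
  fit <- lm(fine ~ days, m2[m2$days %in% c(95, 354), ])
  expect_equal(unname(predict(fit, data.frame(days = 41))),
               m2$fine[m2$days == 41], tolerance = 1e-3)
})
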