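## Synthetic tile-scan campaigns: particle placement, shape rasterisation,
## frame rendering and packaged reference campaigns.

#' Imaging geometry presets
#'
#' The desk preset tiles a full-height strip of the 8 x 8 mm window with a
#' small number of frames (4 at low zoom, 16 at high zoom); the full preset
#' reproduces flight-scale acquisition (30 low-zoom and 1452 high-zoom frames
#' covering the whole window). Imaged strips always span the full flow (y)
#' axis so that y-gradients average out of density estimates.
#'
#' @param preset "desk" or "full".
#' @return Named list of imaging parameters (see \linkS4class{CampaignConfig}).
#' @export
imagingPreset <- function(preset = c("desk", "full")) {
  preset <- match.arg(preset)
  base <- list(pixelSizeLow = 2.2, pixelSizeHigh = 0.22, windowUm = 8000,
               background = 200, particleLevelLow = 60,
               particleLevelHigh = 130, haloDepth = 6)
  if (preset == "desk") {
    c(base, list(stripWidthLowUm = 2000, gridLow = c(1L, 4L),
                 stripWidthHighUm = 200, gridHigh = c(1L, 16L)))
  } else {
    c(base, list(stripWidthLowUm = 8000, gridLow = c(5L, 6L),
                 stripWidthHighUm = 8000, gridHigh = c(33L, 44L)))
  }
}

#' Construct a CampaignConfig
#'
#' @param name Campaign label.
#' @param exposureDays Exposure duration, days.
#' @param occupancyRate Occupancy rate eta in [0, 1].
#' @param coarseDensity,fineDensity Particle densities, per mm^2.
#' @param macroRate Expected macroscopic objects per 8 x 8 mm window.
#' @param sizeModelCoarse,sizeModelFine,sizeModelMacro Log-normal size models
#'   \code{list(family, mode, sdlog, support)}; supports are half-open
#'   \code{[lo, hi)} and default to the class bounds.
#' @param shapeMixCoarse,shapeMixFine Named proportions over shape families.
#' @param gradient List(type, strengthCoarse, strengthFine). Positive
#'   strength concentrates particles towards the aperture (y = 0).
#' @param noiseSd Background noise SD, grey levels.
#' @param imaging Imaging geometry list, see \code{\link{imagingPreset}}.
#' @param seed Integer seed stored with the config.
#' @return A validated \linkS4class{CampaignConfig}.
#' @export
campaignConfig <- function(name = "campaign", exposureDays = 354,
                           occupancyRate = 1, coarseDensity = 2,
                           fineDensity = 4, macroRate = 0,
                           sizeModelCoarse = list(family = "lognormal",
                                                  mode = 155, sdlog = 0.5,
                                                  support = c(50, 1500)),
                           sizeModelFine = list(family = "lognormal",
                                                mode = 3, sdlog = 1,
                                                support = c(0.5, 50)),
                           sizeModelMacro = list(family = "lognormal",
                                                 mode = 82000, sdlog = 0.3,
                                                 support = c(1500, 1e6)),
                           shapeMixCoarse = c(hexagonal_disc = 0.25,
                                              fiber = 0.25,
                                              angular_crystal = 0.3,
                                              parallelepiped_aggregate = 0.2),
                           shapeMixFine = c(coccus = 0.55,
                                            dividing_coccus_with_halo = 0.35,
                                            fiber = 0.1),
                           gradient = list(type = "none", strengthCoarse = 0,
                                           strengthFine = 0),
                           noiseSd = 5, imaging = imagingPreset("desk"),
                           seed = 1L) {
  new("CampaignConfig", name = name, exposureDays = exposureDays,
      occupancyRate = occupancyRate, coarseDensity = coarseDensity,
      fineDensity = fineDensity, macroRate = macroRate,
      sizeModelCoarse = sizeModelCoarse, sizeModelFine = sizeModelFine,
      sizeModelMacro = sizeModelMacro, shapeMixCoarse = shapeMixCoarse,
      shapeMixFine = shapeMixFine, gradient = gradient, noiseSd = noiseSd,
      imaging = imaging, seed = as.integer(seed))
}

## Seeded densities (per mm^2) for the packaged campaigns. Long-duration
## values are the printed per-window means; the intermediate MATISS-2
## timepoints lie on the linear accumulation through the printed points
## (coarse through the origin, fine with its fitted intercept).
.referenceTable <- function() {
  data.frame(
    campaign = c("MATISS-1", "MATISS-2", "MATISS-2", "MATISS-2", "MATISS-2.5"),
    days = c(193, 41, 95, 354, 365),
    coarse = c(2.45, 0.2328, 0.5394, 2.01, 0.36),
    fine = c(4.45, 3.641, 3.820, 4.68, 1.02),
    eta = c(1, 0.35, 0.35, 1, 0.35),
    macroRate = c(1.6, 0.35, 0.8, 3, 0.5))
}

#' Packaged reference campaign configurations
#'
#' Returns a CampaignConfig whose seeded densities reproduce the printed
#' per-window mean densities of the named campaign and timepoint; size-model
#' modes, gradients and the macroscopic-object model carry the remaining
#' published campaign characteristics (coarse mode 155 um^2; coarse particles
#' accumulated towards the aperture, fine away from it; overall coverage of
#' the 354-day campaign near 0.5 %/year).
#'
#' @param campaign One of "MATISS-1", "MATISS-2", "MATISS-2.5".
#' @param timepoint Exposure duration in days; must be a reported timepoint
#'   (193; 41, 95, 354; 365 respectively).
#' @param imaging Imaging geometry override (defaults to the desk preset).
#' @param seed Seed stored with the config.
#' @return A \linkS4class{CampaignConfig}.
#' @export
referenceConfig <- function(campaign, timepoint,
                            imaging = imagingPreset("desk"), seed = 20160101) {
  tab <- .referenceTable()
  row <- tab[tab$campaign == campaign & tab$days == timepoint, ]
  if (nrow(row) != 1L)
    stop("no packaged reference campaign for (", campaign, ", ", timepoint,
         " days)")
  campaignConfig(
    name = paste0(campaign, "-", timepoint, "d"),
    exposureDays = row$days, occupancyRate = row$eta,
    coarseDensity = row$coarse, fineDensity = row$fine,
    macroRate = row$macroRate,
    gradient = list(type = "exponential", strengthCoarse = 1.5,
                    strengthFine = -1.5),
    imaging = imaging, seed = seed)
}

#' List the packaged reference campaign/timepoint pairs
#' @return data.frame of campaign, days, seeded densities, eta and macro rate.
#' @export
referenceCampaigns <- function() .referenceTable()

.sizeModel <- function(config, class) {
  switch(class,
         coarse = config@sizeModelCoarse,
         fine = config@sizeModelFine,
         macroscopic = config@sizeModelMacro,
         stop("unknown size class '", class, "'"))
}

#' Draw particle areas from a class size model
#'
#' Inverse-CDF sampling from the log-normal truncated to the half-open class
#' support; the meanlog is set so the untruncated mode equals the configured
#' mode (meanlog = log(mode) + sdlog^2).
#'
#' @param config A CampaignConfig.
#' @param class "coarse", "fine" or "macroscopic".
#' @param n Number of draws.
#' @return Numeric vector of areas, um^2.
#' @export
drawAreas <- function(config, class, n) {
  sm <- .sizeModel(config, class)
  if (n == 0L) return(numeric())
  mu <- log(sm$mode) + sm$sdlog^2
  lo <- stats::plnorm(sm$support[1], mu, sm$sdlog)
  hi <- stats::plnorm(sm$support[2], mu, sm$sdlog)
  stats::qlnorm(lo + stats::runif(n) * (hi - lo), mu, sm$sdlog)
}

#' Draw a Poisson particle count for one window
#'
#' Counts are Poisson with mean density x window area, the independent
#' aerosol-deposition model behind all seeded densities. For the
#' "macroscopic" class the configured per-window rate is scaled by
#' windowArea / 64 mm^2.
#'
#' @param config A CampaignConfig.
#' @param class "coarse", "fine" or "macroscopic".
#' @param windowArea Window area in mm^2 (default 64).
#' @return Integer count.
#' @export
drawParticleCount <- function(config, class, windowArea = 64) {
  if (windowArea < 0) stop("windowArea must be >= 0")
  mean <- switch(class,
                 coarse = config@coarseDensity * windowArea,
                 fine = config@fineDensity * windowArea,
                 macroscopic = config@macroRate * windowArea / 64,
                 stop("unknown size class '", class, "'"))
  if (mean < 0) stop("negative density")
  stats::rpois(1L, mean)
}

## Inverse-CDF sample of y positions under the configured flow-axis gradient.
.sampleY <- function(config, class, n, H) {
  g <- config@gradient
  s <- if (class == "fine") g$strengthFine else g$strengthCoarse
  u <- stats::runif(n)
  if (g$type == "none" || abs(s) < 1e-12) return(u * H)
  if (g$type == "exponential") {
    # density proportional to exp(-s y / H); s > 0 peaks at the aperture
    return(-H / s * log(1 - u * (1 - exp(-s))))
  }
  # linear: density proportional to 1 + s (1/2 - y/H), clipped to |s| <= 2
  s <- max(-2, min(2, s))
  a <- 1 + s / 2
  y <- if (abs(s) < 1e-12) u * H else
    H * (a - sqrt(a * a - 2 * s * u)) / s
  pmin(pmax(y, 0), H * (1 - 1e-12))
}

#' Place particles of one size class in the window
#'
#' Positions are i.i.d.: uniform in x, and along y either uniform or following
#' the configured gradient. Areas come from the class size model; each
#' particle also receives a shape family (from the class shape mix), a random
#' orientation, an aspect ratio and a deterministic per-particle shape seed so
#' that rasterisation is reproducible independently of the noise stream.
#'
#' @param config A CampaignConfig.
#' @param count Number of particles (>= 0).
#' @param class "coarse", "fine" or "macroscopic".
#' @return Ground-truth data.frame with columns id, x_um, y_um, nominal_um2,
#'   area_um2 (rendered area, filled by \code{\link{renderWindow}}), shape,
#'   class, angle, aspect, shapeSeed.
#' @export
placeParticles <- function(config, count, class = "coarse") {
  if (count < 0) stop("count must be >= 0")
  H <- config@imaging$windowUm
  mix <- switch(class, coarse = config@shapeMixCoarse,
                fine = config@shapeMixFine,
                macroscopic = c(angular_crystal = 1))
  if (count == 0L)
    return(data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      nominal_um2 = numeric(), area_um2 = numeric(),
                      shape = character(), class = character(),
                      angle = numeric(), aspect = numeric(),
                      shapeSeed = numeric()))
  areas <- drawAreas(config, class, count)
  data.frame(
    id = seq_len(count),
    x_um = stats::runif(count) * H,
    y_um = .sampleY(config, class, count, H),
    nominal_um2 = areas,
    area_um2 = areas,
    shape = sample(names(mix), count, replace = TRUE, prob = mix),
    class = class,
    angle = stats::runif(count) * pi,
    aspect = 6 + stats::runif(count) * 6,
    shapeSeed = floor(stats::runif(count) * 1e6))
}

## --- shape rasterisation -------------------------------------------------

## deterministic pseudo-random numbers in [0,1) from a particle's shape seed
.hash01 <- function(seed, k) {
  x <- sin(seed * 12.9898 + k * 78.233) * 43758.5453
  x - floor(x)
}

## point-in-shape over a local pixel grid; dx, dy in pixel units relative to
## the particle centre, f is the linear scale factor
.shapeTest <- function(shape, dx, dy, f, aspect, seed) {
  switch(shape,
    coccus = {
      r <- f
      dx * dx + dy * dy <= r * r
    },
    dividing_coccus_with_halo = {
      r <- f
      d1 <- (dx - 0.6 * r)^2 + dy^2
      d2 <- (dx + 0.6 * r)^2 + dy^2
      d1 <= r * r | d2 <= r * r
    },
    hexagonal_disc = {
      ap <- f * sqrt(3) / 2  # apothem of hexagon with circumradius f
      keep <- abs(dx) <= ap
      for (th in c(pi / 3, 2 * pi / 3))
        keep <- keep & abs(dx * cos(th) + dy * sin(th)) <= ap
      keep
    },
    fiber = {
      w <- f
      L <- aspect * w
      t <- pmin(pmax(dx, -L / 2), L / 2)
      (dx - t)^2 + dy^2 <= (w / 2)^2
    },
    angular_crystal = {
      nv <- 5L + (floor(.hash01(seed, 0) * 3))  # 5-7 vertices, wound CCW
      th <- 2 * pi * (seq_len(nv) - 1) / nv +
        0.5 * vapply(seq_len(nv), function(k) .hash01(seed, k) - 0.5, 1)
      rr <- f * (0.7 + 0.6 * vapply(seq_len(nv), function(k)
        .hash01(seed, k + 10), 1))
      vx <- rr * cos(th); vy <- rr * sin(th)
      keep <- rep(TRUE, length(dx))
      for (i in seq_len(nv)) {
        j <- if (i == nv) 1L else i + 1L
        cross <- (vx[j] - vx[i]) * (dy - vy[i]) - (vy[j] - vy[i]) * (dx - vx[i])
        keep <- keep & cross >= 0
      }
      keep
    },
    parallelepiped_aggregate = {
      keep <- rep(FALSE, length(dx))
      for (b in 0:2) {
        ox <- f * (.hash01(seed, 20 + b) - 0.5)
        oy <- f * (.hash01(seed, 30 + b) - 0.5)
        hw <- f * (0.35 + 0.3 * .hash01(seed, 40 + b))
        hh <- f * (0.35 + 0.3 * .hash01(seed, 50 + b))
        a2 <- (b - 1) * 0.5
        ca <- cos(a2); sa <- sin(a2)
        ux <- (dx - ox) * ca + (dy - oy) * sa
        uy <- -(dx - ox) * sa + (dy - oy) * ca
        keep <- keep | (abs(ux) <= hw & abs(uy) <= hh)
      }
      keep
    },
    stop("unknown shape family '", shape, "'"))
}

## Rasterise one particle so its pixel count matches the nominal area as
## closely as the grid allows (secant step plus bisection on the linear
## scale). Returns relative pixel offsets of the mask (and halo for
## halo-bearing shapes) so stamping avoids any matrix scan.
rasterParticle <- function(shape, nominalUm2, angle, aspect, shapeSeed,
                           pxSize, halo = FALSE) {
  target <- max(1L, round(nominalUm2 / pxSize^2))
  # initial scale guess per family (linear px units) and grid factor large
  # enough to contain the shape over the whole search range
  f0 <- switch(shape,
    coccus = sqrt(target / pi),
    dividing_coccus_with_halo = sqrt(target / 5.389),
    hexagonal_disc = sqrt(target / 2.598),
    fiber = sqrt(target / aspect),
    angular_crystal = sqrt(target / 2.2),
    parallelepiped_aggregate = sqrt(target / 2.6))
  extFactor <- switch(shape,
    coccus = 1, dividing_coccus_with_halo = if (halo) 2.4 else 1.7,
    hexagonal_disc = 1.05, fiber = aspect / 2 + 1, angular_crystal = 1.35,
    parallelepiped_aggregate = 1.5)
  ext <- ceiling(1.45 * f0 * extFactor) + 2L
  n <- 2L * ext + 1L
  # deterministic sub-pixel centre offset: breaks the coarse count
  # quantisation of pixel-centred shapes so the search can hit the target
  dx0 <- .hash01(shapeSeed, 97) - 0.5
  dy0 <- .hash01(shapeSeed, 98) - 0.5
  off <- seq_len(n) - (ext + 1L)
  gx <- matrix(off - dx0, n, n, byrow = TRUE)
  gy <- matrix(off - dy0, n, n)
  ca <- cos(angle); sa <- sin(angle)
  dx <- gx * ca + gy * sa
  dy <- -gx * sa + gy * ca
  evalAt <- function(f) .shapeTest(shape, dx, dy, f, aspect, shapeSeed)
  best <- evalAt(f0); bestCnt <- sum(best); bestErr <- abs(bestCnt - target)
  if (bestErr > 0) {
    # secant step towards the target count, then a short bisection
    f1 <- f0 * sqrt(target / max(bestCnt, 1))
    m1 <- evalAt(f1); c1 <- sum(m1)
    if (abs(c1 - target) < bestErr) {
      best <- m1; bestErr <- abs(c1 - target); bestCnt <- c1
    }
    lof <- min(f0, f1); hif <- max(f0, f1)
    if (c1 != target && bestErr > 0) {
      if (c1 < target) { lof <- f1; hif <- max(hif, f1 * 1.25) }
      if (c1 > target) { hif <- f1; lof <- min(lof, f1 * 0.8) }
      for (it in 1:7) {
        f <- (lof + hif) / 2
        m <- evalAt(f); cnt <- sum(m)
        if (abs(cnt - target) < bestErr) {
          best <- m; bestErr <- abs(cnt - target); bestCnt <- cnt
        }
        if (cnt == target) break
        if (cnt < target) lof <- f else hif <- f
      }
    }
  }
  idx <- which(best)
  rr <- ((idx - 1L) %% n) - ext
  cc <- ((idx - 1L) %/% n) - ext
  out <- list(rr = rr, cc = cc, ext = ext, areaPx = length(idx))
  if (halo && shape == "dividing_coccus_with_halo") {
    r <- sqrt(length(idx) / 5.389)
    d2 <- dx * dx + dy * dy
    hm <- which(!best & d2 >= (1.7 * r)^2 & d2 <= (2.3 * r)^2)
    out$haloRR <- ((hm - 1L) %% n) - ext
    out$haloCC <- ((hm - 1L) %/% n) - ext
  }
  out
}

## frame geometry for one zoom level: origins tile a centred full-height strip
.frameLayout <- function(config, zoom) {
  im <- config@imaging
  px <- if (zoom == "low") im$pixelSizeLow else im$pixelSizeHigh
  grid <- if (zoom == "low") im$gridLow else im$gridHigh
  strip <- if (zoom == "low") im$stripWidthLowUm else im$stripWidthHighUm
  W <- im$windowUm
  nx <- grid[1]; ny <- grid[2]
  fw <- max(8L, floor(strip / nx / px))   # frame width, px
  fh <- max(8L, floor(W / ny / px))       # frame height, px
  x00 <- (W - nx * fw * px) / 2
  origins <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  origins <- data.frame(
    frame = seq_len(nrow(origins)),
    x0_um = x00 + origins$ix * fw * px,
    y0_um = origins$iy * fh * px)
  list(px = px, frameDim = c(fh, fw), origins = origins)
}

## brightness offsets of the red and green channels over the blue scene
.CHANNEL_OFFSETS <- c(R = 18L, G = 8L)

## grey-scale average consistent with the synthetic channel model
.grayFromBlue <- function(B) {
  g <- round((pmin(B + .CHANNEL_OFFSETS[["R"]], 255L) +
                pmin(B + .CHANNEL_OFFSETS[["G"]], 255L) + B) / 3)
  matrix(as.integer(g), nrow(B), ncol(B))
}

## Render the blue (segmentation) channel of a single frame from truth +
## config; the raster cache built by renderWindow avoids re-rasterising
## particles for every frame and pass.
renderFrameBlue <- function(truth, config, zoom, stack, i, frameSeed) {
  im <- config@imaging
  px <- stack@pixelSize
  nr <- stack@frameDim[1]; nc <- stack@frameDim[2]
  o <- stack@frameOrigins[i, ]
  level <- if (zoom == "low") im$particleLevelLow else im$particleLevelHigh
  B <- cpp_gauss_frame(nr, nc, im$background, config@noiseSd, frameSeed)
  cache <- stack@generator$rasterCache
  if (nrow(truth)) {
    maxR <- 1.45 * sqrt(pmax(truth$nominal_um2, 1)) / px *
      ifelse(truth$shape == "fiber", sqrt(truth$aspect), 2.4) + 4
    cx <- (truth$x_um - o$x0_um) / px + 0.5
    cy <- (truth$y_um - o$y0_um) / px + 0.5
    hit <- which(cx > -maxR & cx < nc + maxR & cy > -maxR & cy < nr + maxR)
    for (j in hit) {
      rp <- cache[[j]]
      if (is.null(rp))
        rp <- rasterParticle(truth$shape[j], truth$nominal_um2[j],
                             truth$angle[j], truth$aspect[j],
                             truth$shapeSeed[j], px, halo = zoom == "high")
      B <- .stamp(B, rp$rr, rp$cc, round(cy[j]), round(cx[j]), value = level)
      if (!is.null(rp$haloRR))
        B <- .stamp(B, rp$haloRR, rp$haloCC, round(cy[j]), round(cx[j]),
                    delta = -im$haloDepth)
    }
  }
  macros <- stack@generator$macros
  if (!is.null(macros) && nrow(macros)) {
    for (j in seq_len(nrow(macros)))
      B <- .stampMacro(B, macros[j, ], o, px, zoom, level)
  }
  B[B < 0L] <- 0L
  B
}

## Full RGB frame: the red and green channels carry the same scene slightly
## brighter, so segmentation on the blue component sees the deepest contrast.
renderFrame <- function(truth, config, zoom, stack, i, frameSeed) {
  B <- renderFrameBlue(truth, config, zoom, stack, i, frameSeed)
  Rch <- pmin(B + .CHANNEL_OFFSETS[["R"]], 255L)
  Gch <- pmin(B + .CHANNEL_OFFSETS[["G"]], 255L)
  array(c(Rch, Gch, B), dim = c(nrow(B), ncol(B), 3L))
}

## stamp relative pixel offsets onto a frame matrix
.stamp <- function(frame, rr, cc, r0, c0, value = NULL, delta = NULL) {
  if (!length(rr)) return(frame)
  rr <- rr + r0
  cc <- cc + c0
  keep <- rr >= 1L & rr <= nrow(frame) & cc >= 1L & cc <= ncol(frame)
  if (!any(keep)) return(frame)
  lin <- (cc[keep] - 1L) * nrow(frame) + rr[keep]
  if (!is.null(value)) frame[lin] <- as.integer(value)
  else frame[lin] <- frame[lin] + as.integer(delta)
  frame
}

## macroscopic object: dark body plus, at high zoom, a deep shadow whose dip
## profile depth*(1 - (d/R)^4) fades only at the rim
.stampMacro <- function(frame, mo, origin, px, zoom, level) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx <- (mo$x_um - origin$x0_um) / px + 0.5
  cy <- (mo$y_um - origin$y0_um) / px + 0.5
  rObj <- sqrt(mo$area_um2 / pi) / px
  rSh <- if (zoom == "high") 3 * rObj else rObj
  if (cx < -rSh || cx > nc + rSh || cy < -rSh || cy > nr + rSh) return(frame)
  r0 <- max(1L, floor(cy - rSh)); r1 <- min(nr, ceiling(cy + rSh))
  c0 <- max(1L, floor(cx - rSh)); c1 <- min(nc, ceiling(cx + rSh))
  if (r0 > r1 || c0 > c1) return(frame)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
  sub <- frame[rr, cc, drop = FALSE]
  if (zoom == "high") {
    d <- sqrt(d2)
    dip <- 80 * pmax(0, 1 - (d / rSh)^4)
    sub <- sub - as.integer(round(dip))
  }
  sub[d2 <= rObj^2] <- as.integer(level)
  frame[rr, cc] <- sub
  frame
}

#' Render a window's tile-scan stack from ground truth
#'
#' Produces the RGB frame stack for one zoom level: Gaussian background noise,
#' particles stamped dark on the blue channel (halo-bearing fine shapes get a
#' faint annulus at high zoom that is not part of the ground-truth area), and
#' per-frame seeds drawn from the current RNG stream so rendering is
#' deterministic given the seed state. The rendered pixel area of every
#' particle (deterministic given the truth table) is written back into the
#' returned stack's ground truth.
#'
#' @param truth Ground-truth table from \code{\link{placeParticles}} (rows of
#'   several classes may be concatenated).
#' @param zoom "low" or "high".
#' @param config A CampaignConfig.
#' @param lazy If TRUE frames are re-rendered on access instead of stored.
#' @return A \linkS4class{FrameStack} whose \code{generator$truth} carries the
#'   rendered areas.
#' @export
renderWindow <- function(truth, zoom = c("low", "high"), config,
                         lazy = FALSE) {
  zoom <- match.arg(zoom)
  lay <- .frameLayout(config, zoom)
  smallest <- min(config@sizeModelFine$support[1],
                  if (nrow(truth)) min(truth$nominal_um2) else Inf)
  if (zoom == "high" && smallest / lay$px^2 < 4)
    stop("pixel size ", lay$px, " um does not resolve the smallest ",
         "configured particle (needs >= ~4 px of area)")
  nFr <- nrow(lay$origins)
  frameSeeds <- sample.int(.Machine$integer.max, nFr, replace = TRUE)
  # rasterise once per particle; only particles whose raster can reach the
  # imaged strip are cached (and get their rendered area recorded), the rest
  # keep their nominal area
  cache <- vector("list", nrow(truth))
  if (nrow(truth)) {
    x0 <- min(lay$origins$x0_um)
    x1 <- max(lay$origins$x0_um) + lay$frameDim[2] * lay$px
    pad <- 1.45 * sqrt(pmax(truth$nominal_um2, 1)) *
      ifelse(truth$shape == "fiber", sqrt(truth$aspect), 2.4) + 4 * lay$px
    near <- which(truth$x_um > x0 - pad & truth$x_um < x1 + pad)
    for (j in near) {
      cache[[j]] <- rasterParticle(truth$shape[j], truth$nominal_um2[j],
                                   truth$angle[j], truth$aspect[j],
                                   truth$shapeSeed[j], lay$px,
                                   halo = zoom == "high")
      truth$area_um2[j] <- cache[[j]]$areaPx * lay$px^2
    }
  }
  stack <- new("FrameStack", frames = list(), zoom = zoom, pixelSize = lay$px,
               frameDim = as.integer(lay$frameDim),
               frameOrigins = lay$origins, bitDepth = 8,
               windowUm = config@imaging$windowUm,
               generator = list(truth = truth, config = config,
                                frameSeeds = frameSeeds, macros = NULL,
                                rasterCache = cache),
               metadata = list(exposureDays = config@exposureDays,
                               campaign = config@name))
  if (!lazy)
    stack@frames <- lapply(seq_len(nFr), function(i)
      renderFrame(truth, config, zoom, stack, i, frameSeeds[i]))
  stack
}

#' Ground truth carried by a rendered stack
#' @param stack A FrameStack produced by \code{\link{renderWindow}}.
#' @return The ground-truth data.frame including rendered areas and any
#'   injected macroscopic objects.
#' @export
groundTruth <- function(stack) {
  rbind(stack@generator$truth,
        if (!is.null(stack@generator$macros))
          stack@generator$macros[names(stack@generator$truth)])
}

#' Inject a macroscopic shadow-casting object into a stack
#'
#' Adds one object of area > 1500 um^2. At high zoom the object casts a deep
#' circular shadow of three times its radius that masks small particles in
#' the frames it covers; at low zoom the object is rendered without a
#' penumbra. A frame is listed as affected when the shadow's dark core covers
#' at least \code{affectedMinFraction} of it, which is the bookkeeping used to
#' validate shadow-frame rejection.
#'
#' @param stack A FrameStack (eager stacks are re-materialised).
#' @param area_um2 Object area; drawn from the config's macroscopic size
#'   model when NULL.
#' @param position c(x_um, y_um); uniform over the imaged strip when NULL.
#' @param affectedMinFraction Minimum covered frame fraction for a frame to
#'   be reported as affected.
#' @return list(stack = updated FrameStack, affectedFrames = integer vector).
#' @export
injectMacroscopicObject <- function(stack, area_um2 = NULL, position = NULL,
                                    affectedMinFraction = 0.1) {
  config <- stack@generator$config
  if (is.null(area_um2)) area_um2 <- drawAreas(config, "macroscopic", 1L)
  if (area_um2 <= 1500) stop("macroscopic objects must exceed 1500 um^2")
  if (is.null(position)) {
    b <- imagedBounds(stack)
    position <- c(stats::runif(1, b["x0"], b["x1"]),
                  stats::runif(1, b["y0"], b["y1"]))
  }
  mo <- data.frame(id = NA_integer_, x_um = position[1], y_um = position[2],
                   nominal_um2 = area_um2, area_um2 = area_um2,
                   shape = "coccus", class = "macroscopic", angle = 0,
                   aspect = 1, shapeSeed = 0)
  stack@generator$macros <- rbind(stack@generator$macros, mo)
  aff <- .affectedFrames(stack, mo, affectedMinFraction)
  if (length(stack@frames))  # re-materialise with the object present
    stack@frames <- lapply(seq_len(nFrames(stack)), function(i)
      renderFrame(stack@generator$truth, config, stack@zoom, stack, i,
                  stack@generator$frameSeeds[i]))
  list(stack = stack, affectedFrames = aff)
}

## frames whose footprint is covered by the shadow's dark core beyond the
## given fraction (dark core: dip >= 2 x noise SD)
.affectedFrames <- function(stack, mo, minFraction) {
  if (stack@zoom != "high") return(integer())
  config <- stack@generator$config
  rObj <- sqrt(mo$area_um2 / pi)
  rSh <- 3 * rObj
  depth <- 80
  core <- rSh * (max(0, 1 - 2 * config@noiseSd / depth))^(1 / 4)
  fo <- stack@frameOrigins
  px <- stack@pixelSize
  w <- stack@frameDim[2] * px; h <- stack@frameDim[1] * px
  gx <- (seq_len(20) - 0.5) / 20
  frac <- vapply(seq_len(nrow(fo)), function(i) {
    xs <- fo$x0_um[i] + gx * w
    ys <- fo$y0_um[i] + gx * h
    d2 <- outer((ys - mo$y_um)^2, (xs - mo$x_um)^2, "+")
    mean(d2 <= core^2)
  }, 1)
  which(frac >= minFraction)
}

#' Simulate one complete window
#'
#' Draws per-class Poisson counts, places and renders the particles, and adds
#' Poisson-many macroscopic objects (uniform over the window; only those
#' whose shadow reaches the imaged strip matter downstream).
#'
#' @param config A CampaignConfig.
#' @param zoom "low" or "high".
#' @param lazy Render lazily (recommended beyond toy sizes).
#' @return list(stack, truth, affectedFrames).
#' @export
simulateWindow <- function(config, zoom = c("low", "high"), lazy = TRUE) {
  zoom <- match.arg(zoom)
  truth <- rbind(
    placeParticles(config, drawParticleCount(config, "coarse"), "coarse"),
    placeParticles(config, drawParticleCount(config, "fine"), "fine"))
  truth$id <- seq_len(nrow(truth))
  stack <- renderWindow(truth, zoom, config, lazy = lazy)
  affected <- integer()
  nMacro <- stats::rpois(1L, config@macroRate)
  W <- config@imaging$windowUm
  for (m in seq_len(nMacro)) {
    res <- injectMacroscopicObject(
      stack, position = c(stats::runif(1, 0, W), stats::runif(1, 0, W)))
    stack <- res$stack
    affected <- sort(unique(c(affected, res$affectedFrames)))
  }
  list(stack = stack, truth = groundTruth(stack), affectedFrames = affected)
}
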