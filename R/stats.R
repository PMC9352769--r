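## Campaign statistics: per-window densities, size distributions, flow-axis
## stratification profiles, accumulation kinetics and contamination rate
## versus occupancy rate.

#' Construct a WindowResult
#'
#' @param particles Particle data.frame (see
#'   \code{\link{calibrateDetections}}).
#' @param imagedAreaMm2 Imaged (retained-frame) area, mm^2 (> 0).
#' @param windowId Identifier.
#' @param exposureDays Exposure duration carried along for kinetics.
#' @return A \linkS4class{WindowResult}.
#' @export
windowResult <- function(particles, imagedAreaMm2, windowId = "w1",
                         exposureDays = NA_real_) {
  new("WindowResult", windowId = as.character(windowId),
      imagedAreaMm2 = imagedAreaMm2, particles = particles,
      exposureDays = exposureDays)
}

#' Per-window particle density
#'
#' Exact count / area; no binning is involved.
#'
#' @param window A WindowResult.
#' @param class Size class to count ("coarse", "fine", "macroscopic",
#'   "subresolution"), or "all".
#' @return Particles per mm^2.
#' @export
windowDensity <- function(window, class = "coarse") {
  if (window@imagedAreaMm2 <= 0) stop("window area must be > 0")
  n <- if (class == "all") nrow(window@particles) else
    sum(window@particles$size_class == class)
  n / window@imagedAreaMm2
}

#' Mean, SD and n of per-window densities
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the per-window
#' densities, the quantities drawn as centerlines and error bars on the
#' published dot-plots.
#'
#' @param windows List of WindowResult.
#' @param class Size class.
#' @return list(mean, sd, n, densities).
#' @export
densitySummary <- function(windows, class = "coarse") {
  if (!length(windows)) stop("at least one window is required")
  d <- vapply(windows, windowDensity, 1, class = class)
  list(mean = mean(d), sd = stats::sd(d), n = length(d), densities = d)
}

#' Size histogram and cumulative curve for one class
#'
#' Equal-width bins over the class support (extended upward to cover any
#' larger observed area); the cumulative curve is normalised to the class
#' total. The mode is reported as the midpoint of the maximal bin
#' (\code{\link{modeBin}}).
#'
#' @param particles Particle data.frame or numeric vector of areas (um^2).
#' @param class Size class selected (ignored when a numeric vector is given).
#' @param binWidth Bin width in um^2 (default 50 for coarse, 2.5 for fine).
#' @param bounds Class bounds.
#' @return A \linkS4class{SizeDistribution}.
#' @export
sizeDistribution <- function(particles, class = "coarse", binWidth = NULL,
                             bounds = classBounds()) {
  if (is.null(binWidth)) binWidth <- if (class == "fine") 2.5 else 50
  if (binWidth <= 0) stop("binWidth must be > 0")
  areas <- if (is.numeric(particles)) particles else
    particles$area_um2[particles$size_class == class]
  lo <- switch(class, fine = bounds[["fine"]], coarse = bounds[["coarse"]],
               macroscopic = bounds[["macroscopic"]], subresolution = 0,
               0)
  hi <- switch(class, fine = bounds[["coarse"]],
               coarse = bounds[["macroscopic"]], Inf)
  if (!is.finite(hi)) hi <- max(areas, lo + binWidth)
  if (length(areas)) hi <- max(hi, max(areas))
  edges <- seq(lo, lo + binWidth * ceiling((hi - lo) / binWidth + 1e-9),
               by = binWidth)
  counts <- as.numeric(table(cut(areas, edges, right = FALSE,
                                 include.lowest = FALSE)))
  cumulative <- if (sum(counts)) cumsum(counts) / sum(counts) else
    counts * 0
  new("SizeDistribution", binEdges = edges, counts = counts,
      cumulativeFraction = cumulative, sizeClass = class)
}

#' Particle counts along the flow (y) axis and asymmetry index
#'
#' Equal-width bins over [0, windowHeight) along the flow axis, whose origin
#' is the window side nearest the holder aperture. The asymmetry index is
#' (N_far - N_near) / (N_far + N_near), with near/far the lower/upper half
#' of the window; it is 0 for a symmetric deposition, negative when
#' particles accumulate near the aperture, and reported as NA when no
#' particle is in scope.
#'
#' @param particles Particle data.frame (y_um) or numeric vector of y
#'   positions in um.
#' @param nBins Number of y bins (>= 2).
#' @param windowHeight Window extent along y, um.
#' @return A \linkS4class{SpatialProfile}.
#' @export
spatialProfile <- function(particles, nBins = 16, windowHeight = 8000) {
  if (nBins < 2) stop("nBins must be >= 2")
  y <- if (is.numeric(particles)) particles else particles$y_um
  edges <- seq(0, windowHeight, length.out = nBins + 1)
  counts <- as.numeric(table(cut(y, edges, right = FALSE)))
  near <- sum(y < windowHeight / 2)
  far <- sum(y >= windowHeight / 2)
  ai <- if (near + far == 0) NA_real_ else (far - near) / (far + near)
  new("SpatialProfile", yBinEdges = edges, counts = counts,
      asymmetryIndex = ai)
}

#' Weighted linear fit of density accumulation over exposure time
#'
#' Weighted least squares of density on exposure days with weights 1/SE^2
#' (SE = SD / sqrt(n)); the intercept is fitted, not forced through zero
#' (a forced-zero fit is available via \code{throughOrigin}). If any SE is
#' zero or missing the fit falls back to unweighted least squares and notes
#' it.
#'
#' @param series data.frame with columns days, mean, sd, n (>= 2 rows).
#' @param throughOrigin Force the intercept to zero.
#' @return A \linkS4class{KineticsFit}.
#' @export
fitKinetics <- function(series, throughOrigin = FALSE) {
  if (nrow(series) < 2) stop("at least two timepoints are required")
  se <- series$sd / sqrt(series$n)
  weighted <- all(is.finite(se)) && all(se > 0)
  w <- if (weighted) 1 / se^2 else rep(1, nrow(series))
  if (!weighted)
    message("zero or missing SE: falling back to an unweighted fit")
  fml <- if (throughOrigin) mean ~ days + 0 else mean ~ days
  fit <- stats::lm(fml, data = series, weights = w)
  cf <- stats::coef(fit)
  sl <- if (throughOrigin) cf[["days"]] else cf[["days"]]
  ic <- if (throughOrigin) 0 else cf[["(Intercept)"]]
  slSE <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["days", "Std. Error"]),
    error = function(e) NA_real_)
  new("KineticsFit", slope = unname(sl), intercept = unname(ic),
      slopeSE = unname(slSE), weighted = weighted,
      points = cbind(series, se = se))
}

#' Area-coverage rate in percent of the window per year
#'
#' (sum of particle areas in um^2) / (window area in um^2) x 100 x
#' 365 / exposure days, computed over the requested classes.
#'
#' @param particles Particle data.frame.
#' @param windowAreaMm2 Reference area of the particle list, mm^2.
#' @param exposureDays Exposure duration, days (> 0).
#' @param classes Size classes included (default all detected classes).
#' @return Coverage rate, percent per year.
#' @export
coverageRate <- function(particles, windowAreaMm2, exposureDays,
                         classes = NULL) {
  if (exposureDays <= 0) stop("exposureDays must be > 0")
  if (windowAreaMm2 <= 0) stop("windowAreaMm2 must be > 0")
  a <- if (is.null(classes)) particles$area_um2 else
    particles$area_um2[particles$size_class %in% classes]
  sum(a) / (windowAreaMm2 * 1e6) * 100 * 365 / exposureDays
}

#' Surface contamination rate versus occupancy rate
#'
#' Tabulates (eta, theta) pairs ordered by occupancy rate and checks whether
#' theta is non-decreasing in eta. Theta is the count-based contamination
#' rate in particles/mm^2/day: the fitted slope when a KineticsFit is given,
#' or density / exposure for single-timepoint campaigns. No functional form
#' is fitted.
#'
#' @param fits List of entries, each a list with elements \code{eta} and
#'   either \code{fit} (a KineticsFit) or \code{density} + \code{days};
#'   optional \code{label}, \code{class}.
#' @return data.frame(label, class, eta, theta) ordered by eta, with
#'   attribute \code{monotone} (logical).
#' @export
rateVsOccupancy <- function(fits) {
  if (length(fits) < 2) stop("at least two campaigns are required")
  rows <- lapply(fits, function(f) {
    theta <- if (!is.null(f$fit)) kineticSlope(f$fit) else
      f$density / f$days
    data.frame(label = if (!is.null(f$label)) f$label else NA_character_,
               class = if (!is.null(f$class)) f$class else NA_character_,
               eta = f$eta, theta = theta)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$eta, out$theta), ]
  rownames(out) <- NULL
  attr(out, "monotone") <- !is.unsorted(out$theta)
  out
}
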