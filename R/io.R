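## Formats, configuration and orchestration: TIFF stacks with frame-origin
## sidecars, YAML/JSON configs, the end-to-end pipeline and its run manifest.

#' Write a FrameStack as per-frame TIFFs with a sidecar
#'
#' Frames are written as RGB TIFFs (8-bit, or a 16-bit container for 12-bit
#' data) plus a frame-origin CSV and a JSON metadata sidecar, the on-disk
#' interchange format of the pipeline.
#'
#' @param stack A FrameStack.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of written file paths.
#' @export
writeStack <- function(stack, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^bitDepth(stack) - 1
  bps <- if (bitDepth(stack) == 8) 8L else 16L
  paths <- character(nFrames(stack))
  for (i in seq_len(nFrames(stack))) {
    f <- getFrame(stack, i)
    paths[i] <- file.path(dir, sprintf("%s_%04d.tif", prefix, i))
    tiff::writeTIFF(f / maxval, paths[i], bits.per.sample = bps,
                    compression = "none")
  }
  originPath <- file.path(dir, paste0(prefix, "_origins.csv"))
  utils::write.csv(frameOrigins(stack), originPath, row.names = FALSE)
  metaPath <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(
    list(zoom = zoomLevel(stack), pixelSize = pixelSize(stack),
         bitDepth = bitDepth(stack), windowUm = stack@windowUm,
         frameDim = stack@frameDim, metadata = stack@metadata),
    metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, originPath, metaPath))
}

#' Read a FrameStack written by \code{\link{writeStack}}
#'
#' Validates that every frame shares dimensions; dimension mismatches and a
#' missing sidecar are format errors naming the offending file.
#'
#' @param dir Directory holding the frames and sidecars.
#' @param prefix File-name prefix used at write time.
#' @return A \linkS4class{FrameStack}.
#' @export
readStack <- function(dir, prefix = "frame") {
  if (!dir.exists(dir)) stop("input directory not found: ", dir)
  metaPath <- file.path(dir, paste0(prefix, "_meta.json"))
  originPath <- file.path(dir, paste0(prefix, "_origins.csv"))
  for (p in c(metaPath, originPath))
    if (!file.exists(p)) stop("missing sidecar file: ", p)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  origins <- utils::read.csv(originPath)
  files <- sort(list.files(dir, pattern = paste0("^", prefix,
                                                 "_\\d+\\.tif$"),
                           full.names = TRUE))
  if (length(files) != nrow(origins))
    stop("frame count (", length(files), ") does not match the origin map (",
         nrow(origins), ")")
  maxval <- 2^meta$bitDepth - 1
  frames <- vector("list", length(files))
  dim0 <- NULL
  for (i in seq_along(files)) {
    raw <- tiff::readTIFF(files[i])
    if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
    if (dim(raw)[3] < 3L) stop("non-RGB frame: ", files[i])
    f <- array(as.integer(round(raw[, , 1:3] * maxval)),
               c(dim(raw)[1:2], 3L))
    if (is.null(dim0)) dim0 <- dim(f)
    else if (!identical(dim(f), dim0))
      stop("frame dimensions mismatch in ", files[i])
    frames[[i]] <- f
  }
  new("FrameStack", frames = frames, zoom = meta$zoom,
      pixelSize = meta$pixelSize, frameDim = as.integer(dim0[1:2]),
      frameOrigins = origins, bitDepth = meta$bitDepth,
      windowUm = meta$windowUm, generator = list(),
      metadata = as.list(meta$metadata))
}

#' Save / load a CampaignConfig as YAML or JSON
#'
#' @param config A CampaignConfig.
#' @param path Destination; the extension (.yaml/.yml or .json) picks the
#'   format.
#' @return \code{saveConfig}: the path, invisibly. \code{loadConfig}: a
#'   validated CampaignConfig.
#' @export
saveConfig <- function(config, path) {
  lst <- list(name = config@name, exposureDays = config@exposureDays,
              occupancyRate = config@occupancyRate,
              coarseDensity = config@coarseDensity,
              fineDensity = config@fineDensity, macroRate = config@macroRate,
              sizeModelCoarse = config@sizeModelCoarse,
              sizeModelFine = config@sizeModelFine,
              sizeModelMacro = config@sizeModelMacro,
              shapeMixCoarse = as.list(config@shapeMixCoarse),
              shapeMixFine = as.list(config@shapeMixFine),
              gradient = config@gradient, noiseSd = config@noiseSd,
              imaging = config@imaging, seed = config@seed)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(lst, path)
  else jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveConfig
#' @param path Path to a config written by \code{saveConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  campaignConfig(
    name = lst$name, exposureDays = lst$exposureDays,
    occupancyRate = lst$occupancyRate, coarseDensity = lst$coarseDensity,
    fineDensity = lst$fineDensity, macroRate = lst$macroRate,
    sizeModelCoarse = lapply(lst$sizeModelCoarse, unlist),
    sizeModelFine = lapply(lst$sizeModelFine, unlist),
    sizeModelMacro = lapply(lst$sizeModelMacro, unlist),
    shapeMixCoarse = unlist(lst$shapeMixCoarse),
    shapeMixFine = unlist(lst$shapeMixFine),
    gradient = lst$gradient, noiseSd = lst$noiseSd,
    imaging = lapply(lst$imaging, unlist), seed = lst$seed)
}

#' Segment and summarise one stack into a WindowResult
#'
#' Runs segmentation, calibrates retained detections into particles, and
#' divides by the retained-frame imaged area.
#'
#' @param stack A FrameStack.
#' @param segCfg A SegmentationConfig.
#' @param windowId Identifier for the result.
#' @return A \linkS4class{WindowResult}; the segmentation log is attached as
#'   attribute \code{log}.
#' @export
analyzeStack <- function(stack, segCfg = segmentationConfig(),
                         windowId = "w1") {
  det <- runSegmentation(stack, segCfg)
  parts <- calibrateDetections(det)
  area <- imagedArea(stack, attr(det, "retainedFrames") %||%
                       seq_len(nFrames(stack)))
  wr <- windowResult(parts, area, windowId,
                     exposureDays = stack@metadata$exposureDays %||%
                       NA_real_)
  attr(wr, "log") <- attr(det, "log")
  wr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline: simulate, segment, classify, summarise
#'
#' Simulates \code{nWindows} replicate windows under the campaign config,
#' runs the zoom-appropriate segmentation on each, calibrates particles and
#' aggregates per-window densities. With an output directory, per-stage CSVs
#' and a JSON run manifest (config snapshot, seed, per-stage counts and
#' content hashes of every output file) are written; re-running with the
#' same config and seed reproduces the outputs byte-identically.
#'
#' @param config A CampaignConfig.
#' @param zoom "low" or "high".
#' @param nWindows Number of replicate windows.
#' @param seed Seed for the whole run (defaults to the config's seed).
#' @param segCfg A SegmentationConfig.
#' @param outDir Optional output directory.
#' @return list(windows, summaries, manifest); summaries holds
#'   \code{\link{densitySummary}} results per size class.
#' @export
runPipeline <- function(config, zoom = c("low", "high"), nWindows = 3,
                        seed = config@seed, segCfg = segmentationConfig(),
                        outDir = NULL) {
  zoom <- match.arg(zoom)
  set.seed(seed)
  windows <- vector("list", nWindows)
  stageCounts <- list(framesRead = 0L, framesRejected = 0L, detections = 0L)
  for (w in seq_len(nWindows)) {
    sim <- simulateWindow(config, zoom, lazy = TRUE)
    wr <- analyzeStack(sim$stack, segCfg, windowId = sprintf("w%02d", w))
    lg <- attr(wr, "log")
    stageCounts$framesRead <- stageCounts$framesRead + lg$nFrames
    stageCounts$framesRejected <- stageCounts$framesRejected +
      length(lg$rejectedFrames)
    stageCounts$detections <- stageCounts$detections + lg$nDetections
    windows[[w]] <- wr
  }
  classes <- c("fine", "coarse", "macroscopic")
  summaries <- lapply(classes, function(cl) densitySummary(windows, cl))
  names(summaries) <- classes
  particleTable <- do.call(rbind, lapply(windows, function(w) {
    p <- particles(w)
    if (nrow(p)) cbind(window = w@windowId, p) else NULL
  }))
  if (is.null(particleTable))
    particleTable <- cbind(window = character(),
                           calibrateDetections(
                             data.frame(x_um = numeric(), y_um = numeric(),
                                        area_px = numeric()), pixelSize = 1))
  manifest <- list(
    package = as.character(utils::packageVersion("ParticleScan")),
    campaign = config@name, zoom = zoom, seed = seed, nWindows = nWindows,
    perClassCounts = as.list(table(particleTable$size_class)),
    stageCounts = stageCounts,
    densities = lapply(summaries, function(s) s[c("mean", "sd", "n")]),
    outputs = list())
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    pPath <- file.path(outDir, "particles.csv")
    dPath <- file.path(outDir, "window_densities.csv")
    utils::write.csv(particleTable, pPath, row.names = FALSE)
    utils::write.csv(data.frame(
      window = vapply(windows, function(w) w@windowId, ""),
      imagedArea_mm2 = vapply(windows, windowArea, 1),
      density_fine = vapply(windows, windowDensity, 1, class = "fine"),
      density_coarse = vapply(windows, windowDensity, 1, class = "coarse")),
      dPath, row.names = FALSE)
    cPath <- saveConfig(config, file.path(outDir, "config.json"))
    outs <- c(pPath, dPath, cPath)
    manifest$outputs <- lapply(stats::setNames(as.list(outs),
                                               basename(outs)),
                               function(p) unname(tools::md5sum(p)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(windows = windows, summaries = summaries, manifest = manifest)
}
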