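## Calibration of detections to physical particles and size-class assignment.

#' Default size-class bounds (um^2)
#'
#' Half-open, lower-inclusive intervals: subresolution (0, 0.5), fine
#' [0.5, 50), coarse [50, 1500), macroscopic [1500, Inf). The published
#' captions write strict inequalities on both sides, leaving boundary points
#' unassigned; the lower-inclusive convention used here is explicit and
#' configurable (a tie at 50 um^2 goes coarse).
#'
#' @return Named numeric vector c(fine = 0.5, coarse = 50, macroscopic = 1500).
#' @export
classBounds <- function() c(fine = 0.5, coarse = 50, macroscopic = 1500)

#' Assign a size class from a particle area
#'
#' @param area Numeric vector of areas, um^2 (> 0).
#' @param bounds Named bounds as from \code{\link{classBounds}}.
#' @return Character vector in {subresolution, fine, coarse, macroscopic}.
#' @export
classifyArea <- function(area, bounds = classBounds()) {
  if (any(area <= 0, na.rm = TRUE)) stop("areas must be > 0")
  cut(area, breaks = c(0, bounds, Inf), right = FALSE,
      labels = c("subresolution", names(bounds))) |> as.character()
}

#' Calibrate a detection table into particles
#'
#' Converts pixel areas to um^2 (pixel count x pixelSize^2), carries window
#' coordinates in um, and assigns size classes. Detections flagged as lost
#' during refinement (\code{retained == FALSE}) are excluded.
#'
#' @param det Detection table from \code{\link{runSegmentation}} (or any
#'   data.frame with area_px or area_um2, x_um, y_um).
#' @param pixelSize um per pixel (> 0); defaults to the table's
#'   \code{pixelSize} attribute.
#' @param bounds Size-class bounds.
#' @return Particle data.frame: x_um, y_um, area_um2, elongation,
#'   mean_intensity, size_class.
#' @export
calibrateDetections <- function(det, pixelSize = attr(det, "pixelSize"),
                                bounds = classBounds()) {
  if (is.null(pixelSize) || pixelSize <= 0)
    stop("pixelSize must be > 0")
  if (!is.null(det$retained)) det <- det[det$retained, , drop = FALSE]
  area <- if (!is.null(det$area_um2)) det$area_um2 else
    det$area_px * pixelSize^2
  n <- nrow(det)
  data.frame(
    x_um = det$x_um, y_um = det$y_um, area_um2 = area,
    elongation = if (!is.null(det$elongation)) det$elongation else
      rep(NA_real_, n),
    mean_intensity = if (!is.null(det$mean_intensity))
      det$mean_intensity else rep(NA_real_, n),
    size_class = if (n) classifyArea(area, bounds) else character())
}
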