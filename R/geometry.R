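#' Display geometry
#'
#' Physical description of the presentation display, used to convert pixel
#' distances into degrees of visual angle. Defaults describe a 1024 x 768
#' CRT viewed at 70 cm with ~0.4 mm pixels.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param px_size_mm physical size of one pixel in millimetres.
#' @param viewing_distance_mm eye-to-screen distance in millimetres.
#' @return an object of class `display_geometry`.
#' @export
display_geometry <- function(width_px = 1024, height_px = 768,
                             px_size_mm = 0.4, viewing_distance_mm = 700) {
  vals <- c(width_px, height_px, px_size_mm, viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive")
  structure(list(width_px = width_px, height_px = height_px,
                 px_size_mm = px_size_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "display_geometry")
}

#' Convert a pixel distance to degrees of visual angle
#'
#' Uses the full (non-small-angle) formula
#' `2 * atan(d_px * px_size / (2 * viewing_distance))`.
#'
#' @param distance_px distance on screen in pixels (vectorised).
#' @param geometry a [display_geometry()].
#' @return degrees of visual angle.
#' @export
px_to_deg <- function(distance_px, geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  if (any(distance_px < 0, na.rm = TRUE))
    stop("distance_px must be non-negative")
  2 * atan((distance_px * geometry$px_size_mm) /
             (2 * geometry$viewing_distance_mm)) * 180 / pi
}

#' Convert degrees of visual angle to a pixel distance
#'
#' Inverse of [px_to_deg()].
#'
#' @inheritParams px_to_deg
#' @param deg angle in degrees of visual angle.
#' @return distance in pixels.
#' @export
deg_to_px <- function(deg, geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  2 * geometry$viewing_distance_mm * tan(deg * pi / 360) / geometry$px_size_mm
}
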