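#' Screen and viewing geometry
#'
#' Describes the stimulus monitor and the viewing distance. Screen
#' coordinates used throughout the package are 0-based pixels,
#' `x` in `[0, width_px - 1]` left to right and `y` in `[0, height_px - 1]`
#' top to bottom. A 4:3 panel at 4:3 pixel resolution has square pixels, so
#' a single pixel pitch (cm per pixel, computed from the diagonal) converts
#' any pixel distance to physical length.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_cm Physical diagonal of the display in cm
#'   (default a 17-inch panel).
#' @param viewing_distance_cm Distance from the user's eye to the screen
#'   plane in cm.
#'
#' @return An object of class `screen_geometry` with the given fields plus
#'   `pixel_pitch_cm`, the physical size of one pixel.
#' @examples
#' scr <- screen_geometry()
#' scr$pixel_pitch_cm # ~0.0337 cm
#' @export
screen_geometry <- function(width_px = 1024L, height_px = 768L,
                            diagonal_cm = 17 * 2.54,
                            viewing_distance_cm = 70) {
  stopifnot(width_px > 0, height_px > 0, diagonal_cm > 0,
            viewing_distance_cm > 0)
  s <- list(
    width_px = as.integer(width_px),
    height_px = as.integer(height_px),
    diagonal_cm = diagonal_cm,
    viewing_distance_cm = viewing_distance_cm,
    pixel_pitch_cm = diagonal_cm / sqrt(width_px^2 + height_px^2)
  )
  class(s) <- "screen_geometry"
  s
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("Screen %dx%d px, diagonal %.1f cm, viewed at %.0f cm (pitch %.4f cm/px)\n",
              x$width_px, x$height_px, x$diagonal_cm, x$viewing_distance_cm,
              x$pixel_pitch_cm))
  invisible(x)
}

#' Convert a pixel distance to degrees of visual angle
#'
#' A distance of `e_px` pixels on the screen subtends an angle
#' `atan(e_px * pitch / D)` at the eye, where `pitch` is the pixel pitch
#' and `D` the viewing distance. Accuracy figures expressed in degrees are
#' independent of the screen resolution and of the viewing distance, which
#' makes them comparable across systems. The conversion is applied to RMSE
#' values already aggregated in pixels, not frame by frame.
#'
#' @param e_px Non-negative pixel distance (vectorised).
#' @param screen A [screen_geometry()].
#' @return Angle(s) in degrees.
#' @examples
#' pixels_to_degrees(1, screen_geometry()) # ~0.0276 degrees
#' @export
pixels_to_degrees <- function(e_px, screen) {
  stopifnot(inherits(screen, "screen_geometry"), all(e_px >= 0))
  atan(e_px * screen$pixel_pitch_cm / screen$viewing_distance_cm) * 180 / pi
}

#' Convert degrees of visual angle to a pixel distance
#'
#' Inverse of [pixels_to_degrees()]; used to express feature-noise levels
#' and error budgets in screen pixels.
#'
#' @param deg Angle(s) in degrees.
#' @param screen A [screen_geometry()].
#' @return Pixel distance(s).
#' @export
degrees_to_pixels <- function(deg, screen) {
  stopifnot(inherits(screen, "screen_geometry"))
  tan(deg * pi / 180) * screen$viewing_distance_cm / screen$pixel_pitch_cm
}
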