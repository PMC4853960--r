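#' Screen geometry for gaze-angle conversion
#'
#' Describes the display and viewing setup needed to convert between pixel
#' coordinates and degrees of visual angle. The defaults describe a 24-inch
#' 16:10 panel (1920 x 1200) viewed from 65 cm, sampled at 500 Hz, the setup
#' typical of remote video-oculography in clinical free-viewing experiments.
#'
#' @param width_px,height_px Screen raster size in pixels.
#' @param width_cm,height_cm Physical panel size in centimetres. The pixel and
#'   physical aspect ratios must agree within 1% (square pixels).
#' @param distance_cm Eye-to-screen distance in centimetres.
#' @param sampling_rate_hz Gaze sampling rate in Hz.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' screen_extent_deg(geom)
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1200,
                            width_cm = 51.7, height_cm = 32.3,
                            distance_cm = 65, sampling_rate_hz = 500) {
  vals <- c(width_px = width_px, height_px = height_px, width_cm = width_cm,
            height_cm = height_cm, distance_cm = distance_cm,
            sampling_rate_hz = sampling_rate_hz)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  aspect_px <- width_px / height_px
  aspect_cm <- width_cm / height_cm
  if (abs(aspect_px / aspect_cm - 1) > 0.01) {
    stop("pixel and physical aspect ratios disagree by more than 1% ",
         "(non-square pixels are not supported)", call. = FALSE)
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  ext <- screen_extent_deg(x)
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm at %.1f cm (%.1f x %.1f deg), %g Hz\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm,
              ext[1], ext[2], x$sampling_rate_hz))
  invisible(x)
}

#' Full angular extent of the screen
#'
#' @param geom A [screen_geometry()].
#' @return Named numeric vector `c(width_deg, height_deg)`, the full visual
#'   angle subtended by the screen along each axis.
#' @export
screen_extent_deg <- function(geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  c(width_deg = 2 * atan2(geom$width_cm / 2, geom$distance_cm) * 180 / pi,
    height_deg = 2 * atan2(geom$height_cm / 2, geom$distance_cm) * 180 / pi)
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Positions are expressed relative to the screen centre with `+x` rightward
#' and `+y` upward, using a per-axis arctangent of the physical offset over the
#' viewing distance. The arctangent (rather than a small-angle linear map) is
#' exact at the eccentricities a wide panel reaches (about +/-20 deg).
#' Pixel input follows the raster convention: origin at the top-left corner,
#' `px` growing rightward and `py` growing downward.
#'
#' @param px,py Pixel coordinates (top-left origin).
#' @param geom A [screen_geometry()].
#' @return A data frame with columns `x`, `y` in degrees.
#' @examples
#' g <- screen_geometry()
#' px_to_deg(g$width_px / 2, g$height_px / 2, g)  # centre -> (0, 0)
#' @export
px_to_deg <- function(px, py, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (any(!is.finite(px)) || any(!is.finite(py))) {
    stop("non-finite pixel coordinates", call. = FALSE)
  }
  cm_per_px_x <- geom$width_cm / geom$width_px
  cm_per_px_y <- geom$height_cm / geom$height_px
  dx_cm <- (px - geom$width_px / 2) * cm_per_px_x
  dy_cm <- (geom$height_px / 2 - py) * cm_per_px_y  # flip: +y up
  data.frame(x = atan2(dx_cm, geom$distance_cm) * 180 / pi,
             y = atan2(dy_cm, geom$distance_cm) * 180 / pi)
}

#' Convert degrees of visual angle to pixel coordinates
#'
#' Exact inverse of [px_to_deg()] within the screen bounds.
#'
#' @param x,y Positions in degrees (centre origin, `+x` right, `+y` up).
#' @inheritParams px_to_deg
#' @return A data frame with columns `px`, `py` (top-left origin).
#' @export
deg_to_px <- function(x, y, geom) {
  stopifnot(inherits(geom, "screen_geometry"))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  dx_cm <- tan(x * pi / 180) * geom$distance_cm
  dy_cm <- tan(y * pi / 180) * geom$distance_cm
  data.frame(px = dx_cm * geom$width_px / geom$width_cm + geom$width_px / 2,
             py = geom$height_px / 2 - dy_cm * geom$height_px / geom$height_cm)
}
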