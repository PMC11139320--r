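# Display channel model: gamma calibration from 8-bit pixel values to
# luminance, panel geometry, and conversion between pixel-domain grating
# periods and spatial frequency in cycles per degree of visual angle.

#' Display model
#'
#' Parametric calibration `L(p) = black + (peak - black) * (p/255)^gamma`
#' (gamma 2.4, the standard video-transmission value, by default) plus panel
#' geometry. The default geometry is a 22-inch 16:9 1080p panel viewed at
#' 1.0 m, the midpoint of the clear-vision zone 0.872--1.149 m; a viewing
#' distance outside that zone triggers a warning, not an error. A measured
#' pixel-to-luminance lookup table may replace the parametric curve via
#' `lut` (two-column data frame: `pixel`, `luminance`; linear interpolation).
#'
#' @param gamma display gamma (> 0).
#' @param peak_luminance luminance in cd/m^2 at pixel value 255.
#' @param black_level luminance at pixel value 0.
#' @param pixel_pitch_mm pixel pitch in mm; default derived from a 22-inch
#'   16:9 1920x1080 panel (diagonal 558.8 mm -> 0.2537 mm).
#' @param viewing_distance_m observer distance in metres.
#' @param min_distance_m,max_distance_m clear-vision zone bounds (constants
#'   from the apparatus geometry).
#' @param lut optional calibration table overriding the parametric curve.
#' @return an object of class `display_model`.
#' @export
display_model <- function(gamma = 2.4, peak_luminance = 200,
                          black_level = 0,
                          pixel_pitch_mm = 558.8 * (16 / sqrt(16^2 + 9^2)) / 1920,
                          viewing_distance_m = 1.0,
                          min_distance_m = 0.872, max_distance_m = 1.149,
                          lut = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (peak_luminance <= black_level || black_level < 0)
    stop("need peak_luminance > black_level >= 0")
  if (min_distance_m >= max_distance_m)
    stop("min_distance_m must be < max_distance_m")
  if (pixel_pitch_mm <= 0 || viewing_distance_m <= 0)
    stop("pixel_pitch_mm and viewing_distance_m must be > 0")
  if (viewing_distance_m < min_distance_m ||
      viewing_distance_m > max_distance_m)
    warning("viewing_distance_m is outside the clear-vision zone [",
            min_distance_m, ", ", max_distance_m, "] m")
  if (!is.null(lut)) {
    if (!all(c("pixel", "luminance") %in% names(lut)) || nrow(lut) < 2)
      stop("lut needs columns 'pixel' and 'luminance' and >= 2 rows")
    lut <- lut[order(lut$pixel), ]
  }
  structure(list(gamma = gamma, peak_luminance = peak_luminance,
                 black_level = black_level, pixel_pitch_mm = pixel_pitch_mm,
                 viewing_distance_m = viewing_distance_m,
                 min_distance_m = min_distance_m,
                 max_distance_m = max_distance_m, lut = lut),
            class = "display_model")
}

#' Pixel value to luminance
#'
#' @param p 8-bit pixel value(s) in \[0, 255\].
#' @param dm a [display_model()].
#' @return luminance in cd/m^2; strictly increasing in `p`.
#' @export
pixel_to_luminance <- function(p, dm) {
  stopifnot(inherits(dm, "display_model"))
  if (any(p < 0 | p > 255)) stop("pixel values must lie in [0, 255]")
  if (!is.null(dm$lut))
    return(stats::approx(dm$lut$pixel, dm$lut$luminance, xout = p,
                         rule = 2)$y)
  dm$black_level + (dm$peak_luminance - dm$black_level) * (p / 255)^dm$gamma
}

#' Pixel value whose luminance is closest to a target
#'
#' Used to pick the 8-bit operating level for a luminance-specified operating
#' point (e.g. the 120 cd/m^2 point of the video-quality metric).
#'
#' @param luminance target luminance in cd/m^2.
#' @param dm a [display_model()].
#' @return integer pixel value in \[0, 255\].
#' @export
luminance_to_pixel <- function(luminance, dm) {
  stopifnot(inherits(dm, "display_model"), length(luminance) == 1)
  lum <- pixel_to_luminance(0:255, dm)
  as.integer(which.min(abs(lum - luminance)) - 1L)
}

#' Pixels per degree of visual angle
#'
#' @param dm a [display_model()].
#' @return number of pixels subtending one degree at the viewing distance.
#' @export
pixels_per_degree <- function(dm) {
  stopifnot(inherits(dm, "display_model"))
  2 * dm$viewing_distance_m * 1000 * tan(pi / 360) / dm$pixel_pitch_mm
}

#' Grating period in pixels to spatial frequency in cycles/degree
#'
#' One period of `period_px` pixels subtends the visual angle
#' `2 * atan(period_px * pitch / (2 * distance))`; the spatial frequency is
#' the reciprocal of that angle in degrees. Exact (no small-angle
#' approximation), hence monotone decreasing in `period_px`.
#'
#' @param period_px grating period in pixels (>= 2, vectorised).
#' @param dm a [display_model()].
#' @return spatial frequency in cycles/degree.
#' @export
period_to_cpd <- function(period_px, dm) {
  stopifnot(inherits(dm, "display_model"))
  if (any(period_px < 2)) stop("period_px must be >= 2")
  ang_deg <- 2 * atan(period_px * dm$pixel_pitch_mm /
                        (2 * dm$viewing_distance_m * 1000)) * 180 / pi
  1 / ang_deg
}

#' Spatial frequency in cycles/degree to grating period in pixels
#'
#' Exact inverse of [period_to_cpd()].
#'
#' @param cpd spatial frequency in cycles/degree (> 0, vectorised).
#' @param dm a [display_model()].
#' @return period in pixels.
#' @export
cpd_to_period <- function(cpd, dm) {
  stopifnot(inherits(dm, "display_model"))
  if (any(cpd <= 0)) stop("cpd must be > 0")
  ang_rad <- (1 / cpd) * pi / 180
  2 * dm$viewing_distance_m * 1000 * tan(ang_rad / 2) / dm$pixel_pitch_mm
}
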