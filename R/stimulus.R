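# Mira stimulus synthesis: a vertical sinusoidal grating under a radial Kaiser
# window, blended into a uniform mid-grey background, plus its analytic
# spatial spectrum and the temporal (flicker) modulation channel.

#' Mira stimulus specification
#'
#' Geometric and photometric parameters of the circular "Mira" test pattern:
#' a vertical sinusoidal grating of period `period_px` pixels multiplied by a
#' radial Kaiser window of parameter `kaiser_beta`, occupying a disc of
#' diameter `diameter_px` centred on a `width_px` x `height_px` canvas.
#' Outside the disc the normalized brightness is exactly 1/2, so the pattern
#' blends into a uniform background at the nominal 8-bit `background_level`
#' once mapped to display units with `modulation_amplitude` (see
#' [quantize_to_display()]).
#'
#' @param width_px,height_px canvas size in pixels.
#' @param diameter_px disc diameter in pixels; must fit the canvas.
#' @param kaiser_beta Kaiser window shape parameter (>= 0; 0 = flat disc).
#' @param period_px grating period in pixels (>= 2, the pixel-grid Nyquist).
#' @param background_level nominal 8-bit background pixel value.
#' @param modulation_amplitude peak grating excursion in 8-bit pixel units;
#'   `background_level +/- modulation_amplitude` must stay within \[0, 255\]
#'   so the pattern is never clipped by the 8-bit range.
#' @return an object of class `mira_spec`.
#' @export
mira_spec <- function(width_px, height_px, diameter_px, kaiser_beta = 6,
                      period_px = 32, background_level = 120,
                      modulation_amplitude = 40) {
  stopifnot(width_px >= 1, height_px >= 1)
  if (diameter_px > min(width_px, height_px))
    stop("diameter_px must not exceed min(width_px, height_px)")
  if (kaiser_beta < 0) stop("kaiser_beta must be >= 0")
  if (period_px < 2) stop("period_px must be >= 2 (pixel-grid Nyquist)")
  if (background_level < 0 || background_level > 255)
    stop("background_level must be an 8-bit value")
  if (modulation_amplitude < 0) stop("modulation_amplitude must be >= 0")
  if (background_level - modulation_amplitude < 0 ||
      background_level + modulation_amplitude > 255)
    stop("background_level +/- modulation_amplitude leaves [0, 255]: ",
         "the pattern would be clipped by the 8-bit range")
  structure(list(width_px = width_px, height_px = height_px,
                 diameter_px = diameter_px, kaiser_beta = kaiser_beta,
                 period_px = period_px, background_level = background_level,
                 modulation_amplitude = modulation_amplitude),
            class = "mira_spec")
}

#' Radial Kaiser window
#'
#' The Kaiser taper `I0(beta * sqrt(1 - r^2)) / I0(beta)` where `I0` is the
#' modified Bessel function of the first kind, order zero. It equals 1 at the
#' centre (`r = 0`) and `1 / I0(beta)` at the rim (`r = 1`), and for a given
#' main-lobe width concentrates more spectral energy in the main lobe than a
#' Gaussian taper of comparable support.
#'
#' @param r normalized radius, in \[0, 1\] (vectorised).
#' @param beta window shape parameter, >= 0.
#' @return window weight(s) in `(0, 1]`.
#' @export
kaiser_window <- function(r, beta) {
  if (length(beta) != 1 || is.na(beta) || beta < 0)
    stop("beta must be a single value >= 0")
  if (any(is.na(r)) || any(r < 0) || any(r > 1))
    stop("r must lie in [0, 1]")
  besselI(beta * sqrt(1 - r^2), 0) / besselI(beta, 0)
}

#' Render the Mira pattern, normalized to \[0, 1\]
#'
#' Uses centred pixel coordinates `x0 = x - w/2`, `y0 = y - h/2` (x, y
#' zero-based from the top-left, row-major `[y, x]` indexing) and the
#' normalized radius `r = 2 * sqrt(x0^2 + y0^2) / d`. Inside the disc
#' (`r < 1`) the brightness is
#' `0.5 * (kaiser_window(r, beta) * sin(2*pi*y0 / T) + 1)`; outside it is
#' exactly 1/2.
#'
#' @param spec a [mira_spec()].
#' @return numeric matrix `height_px` x `width_px` with values in \[0, 1\].
#' @export
render_mira <- function(spec) {
  stopifnot(inherits(spec, "mira_spec"))
  x0 <- (seq_len(spec$width_px) - 1) - spec$width_px / 2
  y0 <- (seq_len(spec$height_px) - 1) - spec$height_px / 2
  r <- 2 * sqrt(outer(y0^2, x0^2, "+")) / spec$diameter_px
  img <- matrix(0.5, spec$height_px, spec$width_px)
  inside <- r < 1
  win <- besselI(spec$kaiser_beta * sqrt(1 - pmin(r[inside], 1)^2), 0) /
    besselI(spec$kaiser_beta, 0)
  carrier <- sin(2 * pi * y0 / spec$period_px)  # varies along rows only
  img[inside] <- 0.5 * (win * matrix(carrier, spec$height_px,
                                     spec$width_px)[inside] + 1)
  img
}

#' Map a normalized image to 8-bit display values
#'
#' `pixel = round(level + amplitude * (2 * image01 - 1))`: the background
#' (value 1/2) maps to exactly `level`, and the grating swings by
#' `+/- amplitude` pixel units around it. Errors rather than clips when
#' `level +/- amplitude` leaves the 8-bit range, mirroring the design
#' constraint that the pattern must not be distorted by the hard 8-bit limits.
#'
#' @param image01 numeric matrix in \[0, 1\].
#' @param level 8-bit background value.
#' @param amplitude excursion in 8-bit units.
#' @return integer matrix of 8-bit pixel values.
#' @export
quantize_to_display <- function(image01, level, amplitude) {
  if (any(image01 < 0 | image01 > 1)) stop("image01 must lie in [0, 1]")
  if (level - amplitude < 0 || level + amplitude > 255)
    stop("level +/- amplitude leaves [0, 255]; the 8-bit range would clip")
  out <- round(level + amplitude * (2 * image01 - 1))
  storage.mode(out) <- "integer"
  out
}

#' Analytic spatial spectrum of the Mira grating
#'
#' Closed-form Fourier transform of the Kaiser-windowed grating along the
#' modulated (vertical) axis, as a function of spatial frequency `k` in
#' cycles/pixel. The window of full width `d` (half-width `R = d/2`) has
#' transform proportional to
#' `sinh(sqrt(beta^2 - (2*pi*R*(k - 1/T))^2)) / sqrt(beta^2 - (2*pi*R*(k - 1/T))^2)`,
#' continued analytically to `sin(x)/x` form where the radicand is negative
#' (outside the main lobe). The returned amplitude is normalized to 1 at the
#' carrier frequency `1/T` and is symmetric about it.
#'
#' @param k spatial frequency in cycles/pixel (vectorised).
#' @param spec a [mira_spec()].
#' @return normalized spectral amplitude (signed; sidelobes alternate sign).
#' @export
mira_spectrum <- function(k, spec) {
  stopifnot(inherits(spec, "mira_spec"))
  beta <- spec$kaiser_beta
  R <- spec$diameter_px / 2
  x <- 2 * pi * R * (k - 1 / spec$period_px)
  rad <- beta^2 - x^2
  out <- numeric(length(x))
  pos <- rad > 0
  s <- sqrt(abs(rad))
  out[pos] <- sinh(s[pos]) / s[pos]
  out[!pos] <- ifelse(s[!pos] == 0, 1, sin(s[!pos]) / s[!pos])
  peak <- if (beta > 0) sinh(beta) / beta else 1
  out / peak
}

#' Flicker (temporal modulation) specification
#'
#' The whole-screen brightness is gated in time by pulse-width modulation of
#' the backlight at a carrier rate far above flicker fusion (3.9 kHz by
#' default), so only the envelope at `temporal_frequency_hz` is perceptually
#' relevant; the carrier is retained as metadata but not rendered
#' sample-by-sample.
#'
#' @param temporal_frequency_hz flicker rate in Hz (> 0 unless `m = 0`).
#' @param modulation_depth dimensionless depth `m` in \[0, 1\].
#' @param pwm_carrier_hz PWM carrier rate; must be at least 10x the flicker
#'   rate.
#' @param waveform `"square"` (two-level gating) or `"sine"` (sinusoidal
#'   envelope of the same mean).
#' @return an object of class `flicker_spec`.
#' @export
flicker_spec <- function(temporal_frequency_hz, modulation_depth,
                         pwm_carrier_hz = 3900,
                         waveform = c("square", "sine")) {
  waveform <- match.arg(waveform)
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1]")
  if (temporal_frequency_hz < 0) stop("temporal_frequency_hz must be >= 0")
  if (pwm_carrier_hz < 10 * temporal_frequency_hz)
    stop("pwm_carrier_hz must be at least 10x the flicker frequency")
  structure(list(temporal_frequency_hz = temporal_frequency_hz,
                 modulation_depth = modulation_depth,
                 pwm_carrier_hz = pwm_carrier_hz, waveform = waveform),
            class = "flicker_spec")
}

#' Multiplicative flicker brightness factor at time t
#'
#' Both waveforms share the mean factor `1 / (1 + m)` so that the peak factor
#' is exactly 1 (full brightness) and the time-average luminance is identical
#' across waveforms at a given depth. Square mode alternates between
#' `(1 + m) * mean` and `(1 - m) * mean` with 50% duty; sine mode is
#' `mean * (1 + m * sin(2*pi*f*t))`.
#'
#' @param fspec a [flicker_spec()].
#' @param t time in seconds, >= 0 (vectorised).
#' @return factor(s) in \[0, 1\].
#' @export
flicker_waveform <- function(fspec, t) {
  stopifnot(inherits(fspec, "flicker_spec"))
  if (any(t < 0)) stop("t must be >= 0")
  m <- fspec$modulation_depth
  f <- fspec$temporal_frequency_hz
  mean_factor <- 1 / (1 + m)
  if (m == 0 || f == 0) return(rep(mean_factor, length(t)))
  if (fspec$waveform == "square") {
    phase <- (t * f) %% 1
    mean_factor * (1 + m * ifelse(phase < 0.5, 1, -1))
  } else {
    mean_factor * (1 + m * sin(2 * pi * f * t))
  }
}
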