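# CSF-weighted PSNR video quality metric: the error image between reference
# and distorted frames is filtered in the frequency domain by a perceptual
# weight derived from a CSF surface (convolution theorem), scored as PSNR,
# averaged per sequence, mapped to subjective scores with a 4-parameter
# logistic, and summarized by Pearson correlation with Fisher-z bounds.

#' Aligned reference/distorted frame pair container
#'
#' @param reference,distorted lists of numeric matrices (8-bit luma values,
#'   0--255), equal lengths and dimensions.
#' @param fps frames per second (> 0).
#' @param display a [display_model()] supplying geometry and calibration.
#' @param operating_luminance adapting luminance in cd/m^2 at which the CSF
#'   surface is queried (default 120).
#' @return an object of class `video_pair`.
#' @export
video_pair <- function(reference, distorted, fps = 25,
                       display = display_model(), operating_luminance = 120) {
  if (!is.list(reference)) reference <- list(reference)
  if (!is.list(distorted)) distorted <- list(distorted)
  if (length(reference) != length(distorted) || length(reference) == 0)
    stop("reference and distorted must have the same non-zero frame count")
  for (i in seq_along(reference))
    if (!identical(dim(reference[[i]]), dim(distorted[[i]])))
      stop("frame ", i, ": dimensions differ between reference and distorted")
  if (fps <= 0) stop("fps must be > 0")
  structure(list(reference = reference, distorted = distorted, fps = fps,
                 display = display, operating_luminance = operating_luminance),
            class = "video_pair")
}

# Two-sided DFT bin frequencies in cycles/sample for an n-point transform.
fft_freq <- function(n) {
  i <- seq_len(n) - 1
  ifelse(i <= n / 2, i, i - n) / n
}

#' CSF weight field on the 2-D DFT grid
#'
#' Each DFT bin is assigned the model's contrast sensitivity at the bin's
#' radial spatial frequency (converted from cycles/pixel to cycles/degree via
#' the display geometry), the given temporal frequency, and the operating
#' point: for a polynomial surface, the 8-bit level whose calibrated
#' luminance is closest to `operating_luminance`; for a pyramid surface, the
#' operating luminance directly. Frequencies beyond the surface's calibrated
#' range are clamped to the boundary. Weights are normalized so the peak is
#' 1 and the DC bin is forced to 1 (mean luminance shifts are not "noise").
#'
#' @param model a `csf_model`.
#' @param dims integer c(rows, cols) of the frame.
#' @param display a [display_model()].
#' @param temporal_frequency temporal frequency in Hz of the error signal.
#' @param operating_luminance adapting luminance in cd/m^2.
#' @return numeric matrix of weights in (0, 1], dimensions `dims`.
#' @export
csf_weight_field <- function(model, dims, display = display_model(),
                             temporal_frequency = 0,
                             operating_luminance = 120) {
  stopifnot(inherits(model, "csf_model"), length(dims) == 2)
  ppd <- pixels_per_degree(display)
  vy <- fft_freq(dims[1])
  vx <- fft_freq(dims[2])
  cpd <- ppd * sqrt(outer(vy^2, vx^2, "+"))
  if (inherits(model, "polynomial_csf")) {
    level <- min(luminance_to_pixel(operating_luminance, display),
                 model$l_max)
    f <- min(temporal_frequency, model$f_max)
    ls <- csf_log_sensitivity(model, pmin(as.vector(cpd), model$k_max),
                              f, level)
  } else {
    ls <- csf_log_sensitivity(model, as.vector(cpd), temporal_frequency,
                              operating_luminance)
  }
  w <- matrix(10^ls, dims[1], dims[2])
  w <- w / max(w)
  w[1, 1] <- 1
  w
}

#' CSF-weighted PSNR of a video pair
#'
#' Per frame, the error image (reference minus distorted) is transformed
#' with the 2-D FFT, multiplied by the CSF weight field, and the weighted
#' mean squared error is read off via Parseval's theorem;
#' `PSNR = 10 log10(255^2 / wMSE)`, capped at 100 dB for (near-)identical
#' frames. The sequence score is the arithmetic mean of the per-frame
#' scores. A flat (all-ones) weight field reproduces plain PSNR exactly.
#'
#' The per-frame temporal frequency passed to the weight field is either a
#' fixed number (`temporal = <Hz>`) or, with `temporal = "motion"`, a cheap
#' motion proxy: `fps * gain * mean(|frame_t - frame_(t-1)|) / 255` (0 Hz for
#' the first frame). The proxy is monotone in flicker/motion energy and
#' isolated here so a different estimator can be swapped in.
#'
#' @param pair a [video_pair()].
#' @param model a `csf_model` (or `NULL` for unweighted PSNR).
#' @param temporal `"motion"` or a fixed temporal frequency in Hz.
#' @param motion_gain gain of the motion-to-Hz mapping (default 1).
#' @return list with `per_frame` (dB vector), `sequence` (mean dB), and
#'   `temporal_frequency` (Hz used per frame).
#' @export
weighted_psnr <- function(pair, model = NULL, temporal = "motion",
                          motion_gain = 1) {
  stopifnot(inherits(pair, "video_pair"))
  nfr <- length(pair$reference)
  ft <- numeric(nfr)
  if (is.numeric(temporal)) {
    ft[] <- temporal
  } else {
    for (t in seq_len(nfr)[-1]) {
      ft[t] <- pair$fps * motion_gain *
        mean(abs(pair$reference[[t]] - pair$reference[[t - 1]])) / 255
    }
  }
  scores <- numeric(nfr)
  w_cache <- list()
  for (t in seq_len(nfr)) {
    err <- pair$reference[[t]] - pair$distorted[[t]]
    n_tot <- length(err)
    if (is.null(model)) {
      wmse <- mean(err^2)
    } else {
      key <- sprintf("%.6g", ft[t])
      if (is.null(w_cache[[key]]))
        w_cache[[key]] <- csf_weight_field(model, dim(err), pair$display,
                                           ft[t], pair$operating_luminance)
      spec <- stats::fft(err) * w_cache[[key]]
      wmse <- sum(Mod(spec)^2) / n_tot^2  # Parseval
    }
    scores[t] <- if (wmse < 255^2 * 1e-10) 100 else
      min(10 * log10(255^2 / wmse), 100)
  }
  list(per_frame = scores, sequence = mean(scores), temporal_frequency = ft)
}

#' Weber sensitivity to log10 sensitivity
#'
#' @param sensitivity_weber sensitivity on the linear (Weber) scale, > 0.
#' @return log10 of the input.
#' @export
convert_contrast_units <- function(sensitivity_weber) {
  if (any(sensitivity_weber <= 0)) stop("sensitivity must be > 0")
  log10(sensitivity_weber)
}

#' Fit the VQEG 4-parameter logistic mapping metric -> MOS
#'
#' `MOS_hat(x) = lower + (upper - lower) / (1 + exp(-slope * (x - mid)))`,
#' fitted by least squares with a deterministic data-driven initializer
#' (asymptotes from the MOS range, midpoint at the median metric score).
#'
#' @param scores objective metric outputs (length >= 5).
#' @param mos mean opinion scores, same length, non-constant.
#' @return object of class `logistic_mapping` with elements `lower`,
#'   `upper`, `slope`, `mid`.
#' @export
fit_logistic_mapping <- function(scores, mos) {
  if (length(scores) < 5 || length(scores) != length(mos))
    stop("need >= 5 paired (score, MOS) points")
  if (stats::sd(mos) == 0)
    stop("degenerate fit: MOS has no variance")
  rng <- diff(range(mos))
  start <- list(lower = min(mos) - 0.05 * rng, upper = max(mos) + 0.05 * rng,
                slope = 1 / max(stats::sd(scores), 1e-8),
                mid = stats::median(scores))
  df <- data.frame(x = scores, y = mos)
  fit <- stats::nls(
    y ~ lower + (upper - lower) / (1 + exp(-slope * (x - mid))),
    data = df, start = start, algorithm = "port",
    control = stats::nls.control(maxiter = 1000, warnOnly = TRUE))
  p <- as.list(stats::coef(fit))
  if (p$upper < p$lower) {  # canonical orientation: upper asymptote on top
    p <- list(lower = p$upper, upper = p$lower, slope = -p$slope, mid = p$mid)
  }
  structure(p, class = "logistic_mapping")
}

#' @param object a `logistic_mapping`.
#' @param newdata metric scores to map.
#' @param ... unused.
#' @rdname fit_logistic_mapping
#' @export
predict.logistic_mapping <- function(object, newdata, ...) {
  object$lower + (object$upper - object$lower) /
    (1 + exp(-object$slope * (newdata - object$mid)))
}

#' Pearson correlation with Fisher-z 95% bounds
#'
#' `z = atanh(r)` with standard error `1 / sqrt(n - 3)`; the bounds are
#' `tanh(z -/+ 1.96 se)`. Perfect correlations return degenerate bounds at
#' +/- 1.
#'
#' @param x,y numeric vectors, length >= 4, both non-constant.
#' @return list with `plcc`, `lower`, `upper`, `n`.
#' @export
plcc_with_bounds <- function(x, y) {
  n <- length(x)
  if (n < 4 || n != length(y)) stop("need paired vectors of length >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("inputs must be non-constant")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(plcc = r, lower = r, upper = r, n = n))
  se <- 1 / sqrt(n - 3)
  z <- atanh(r)
  list(plcc = r, lower = tanh(z - 1.96 * se), upper = tanh(z + 1.96 * se),
       n = n)
}
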