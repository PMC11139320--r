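# Shared fixtures: a pyramid ground truth whose thresholds stay inside the
# measurable unit interval over the full experimental grid, and a
# convenience observer around it.

demo_truth <- function() pyramid_csf(c0 = 2.3, c_f = -0.022, c_k = -0.035,
                                     c_L = 0.3)

demo_observer <- function(noise = 0.05, bias = 0) {
  observer_model(demo_truth(), log10_noise_sd = noise,
                 observer_bias_sd = bias)
}

# Independent power-series evaluation of the modified Bessel function I0,
# used as the high-precision oracle for the Kaiser window.
I0_series <- function(x) {
  s <- 0
  for (m in 0:60) s <- s + (x / 2)^(2 * m) / factorial(m)^2
  s
}

# DFT of the rendered central-column profile: the stimulus-spectrum oracle.
# Returns matched-normalized analytic and DFT amplitudes over the main lobe.
spectrum_vs_dft <- function(spec, nfft = 32768, lobe_fraction = 0.999) {
  img <- render_mira(spec)
  xc <- floor(spec$width_px / 2) + 1
  p <- img[, xc] - 0.5
  F <- Mod(stats::fft(c(p, rep(0, nfft - length(p)))))[1:(nfft / 2)]
  nu <- (0:(nfft / 2 - 1)) / nfft
  half_width <- spec$kaiser_beta / (pi * spec$diameter_px)  # main-lobe edge
  main <- abs(nu - 1 / spec$period_px) < half_width * lobe_fraction
  analytic <- abs(mira_spectrum(nu[main], spec))
  list(analytic = analytic / max(analytic), dft = F[main] / max(F[main]),
       nu = nu[main])
}
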