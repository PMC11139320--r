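---
title: "Modelling spatio-temporal contrast sensitivity and weighting video quality by it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatio-temporal contrast sensitivity and weighting video quality by it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscsf)
```

## The measurement model

Early human vision acts as a band-pass filter on spatio-temporal contrast:
only stimulus energy above the contrast threshold is perceived. The contrast
sensitivity function (CSF) summarizes this filter as
$s(k, f, l) = 1/\text{threshold}$, with $k$ spatial frequency in
cycles/degree, $f$ temporal (flicker) frequency in Hz, and $l$ the adapting
background level. `viscsf` models a measurement campaign in which observers,
viewing a modern PWM-backlit LCD without head restraint, raise the
modulation of a test pattern from invisible until it is just detectable (the
method of limits), and fits a smooth surface to the resulting thresholds.

### The Mira stimulus

The test pattern is a vertical sinusoidal grating inside a circular window:
with centred pixel coordinates $(x_0, y_0)$ and normalized radius
$r = 2\sqrt{x_0^2+y_0^2}/d$ for a disc of diameter $d$ pixels,

$$M(x_0, y_0) = \tfrac12\!\left[\frac{I_0(\beta\sqrt{1-r^2})}{I_0(\beta)}
  \sin\!\frac{2\pi y_0}{T} + 1\right] \quad (r < 1), \qquad
  M = \tfrac12 \text{ otherwise},$$

where $I_0$ is the zeroth-order modified Bessel function of the first kind.
The Kaiser taper keeps more of the field near full modulation than a Gabor
(useful when the observer's fixation is not mechanically constrained) while
concentrating spectral energy in the main lobe. A note on the radius
normalization: the source description defines $r$ with $1/d$ while calling
$d$ the *diameter*; those two statements conflict, and we resolve it in
favour of the word "diameter" ($r = 2\,\text{dist}/d$), which is also the
only reading consistent with the closed-form spectrum below. The analytic
amplitude spectrum of the windowed grating along the modulated axis is the
standard Kaiser transform centred on the carrier $1/T$ cycles/pixel,

$$W(\nu) \propto \frac{\sinh\sqrt{\beta^2 - (\pi d (\nu - 1/T))^2}}
  {\sqrt{\beta^2 - (\pi d (\nu - 1/T))^2}},$$

continued as $\sin(x)/x$ outside the main lobe. The printed closed form in
the source is typographically damaged, so `mira_spectrum()` implements this
standard transform and is validated against a zero-padded DFT of the
rendered central-column profile (relative tolerance $10^{-2}$ over the main
lobe, three parameter sets) rather than against the printed string.

Temporal modulation is produced by PWM-gating the backlight at a 3.9 kHz
carrier — far above flicker fusion — so the generator exposes only the
envelope at $f$ Hz. Both waveform modes (square gating and its
sine-equivalent) share the mean factor $1/(1+m)$ at depth $m$, so the peak
factor is 1 and mean luminance is waveform-independent.

### Display channel

Pixel-to-luminance calibration is parametric,
$L(p) = \text{black} + (\text{peak}-\text{black})(p/255)^{\gamma}$ with
$\gamma = 2.4$ (the video-transmission standard), because the measured
calibration curve of the original apparatus is not tabulated; a two-column
lookup table can replace it when real photometer data exist. Geometry
defaults to a 22-inch 16:9 1080p panel (pitch 0.2537 mm) at 1.0 m — the
midpoint of the 0.872–1.149 m clear-vision zone, which we treat as a pair
of constants from the apparatus description. The converter
`period_to_cpd()` uses the exact $\arctan$ expression; note the model
normalizer of 15 cycles/degree is a separate constant and is *not* forced
to agree with the geometric Nyquist frequency of a 2-px period.

### Experiment designs and the stopping rule

Experiment 1 measures uniform-field flicker thresholds: 12 temporal
frequencies × 5 background levels {40, 80, 120, 160, 200}, 13 observers,
780 records. Experiment 2 measures the full spatio-temporal surface: 8
spatial × 12 temporal frequencies × 5 levels, with two recorded adjustments
per condition (flicker visibility on the uniform field first, then pattern
visibility), 29 observers — 960 records per observer, 27840 in total. The
individual frequency values are not published; defaults are log-spaced
within the stated extremes (1–66.6 Hz, 0.5–15 cpd) and fully configurable.
Nothing downstream depends on the particular values, only on the design
cardinalities, which are checked exactly.

Measurement of each condition continues until the BT.500-style 95%
confidence half-width $1.96\,\hat\sigma/\sqrt{n}$ drops below 5% of the
running mean ($z$ rather than $t$ quantile, matching the BT.500 formula and
the large per-condition $n$). `simulate_session(stopping = "on")`
implements exactly this rule per (observer, condition).

## The synthetic observer

Real thresholds are unavailable, so the generator draws

$$t = \frac{1}{s_{\text{true}}(k,f,l)} \cdot 10^{\varepsilon + b},
  \qquad \varepsilon \sim N(0, \sigma), \; b \sim N(0, \sigma_b),$$

clipped to the measurable interval $(0, 1]$: lognormal scatter keeps
thresholds positive and makes the median draw equal the true threshold.
Defaults are $\sigma = 0.05$ log$_{10}$ units — the value the recovery
criterion states — and $\sigma_b = 0$. The bias default is deliberate: the
recovery bound $1.5\sigma/\sqrt{n_{\text{obs}}}$ is a statement about
unbiased scatter, and a shared observer offset is absorbed almost entirely
by the fitted intercept anyway; stable individual offsets seen in real
panels can be switched on via `observer_bias_sd`. The default ground truth
used in examples, fixtures and the pipeline self-check is the pyramid
surface $(c_0, c_f, c_k, c_L) = (2.3, -0.022, -0.035, 0.3)$, chosen once so
that thresholds remain inside $(0,1]$ over the whole design grid (steeper,
more literature-typical slopes would push the corner conditions past 100%
contrast, which the real apparatus could not display either). What a green
recovery test establishes is therefore that the pipeline is statistically
faithful to its own noise model — not that human data would be fitted this
well; the generator has no lapses, no learning, no fatigue, and no
frequency-dependent variance.

All randomness flows from one master seed; per-observer streams are split
off by hashing the participant label, so any subset of observers
reproduces bit-for-bit.

## Fitting

The published anomalous-flicker conditions — (15, 200), (40, 200),
(36, 160), (13, 80), (20, 80), (48, 80), (40, 40), (46, 40) in
(Hz, level) — are equipment artefacts (spurious spectral maxima of the
PWM/LCD chain) and ship as a default exclusion list applied before
aggregation; they are data about the display, not about vision.

Aggregation averages thresholds within a condition *first* and then takes
$\log_{10}$ of the inverse (average-then-log, matching the definition of
the response vector as the logarithm of the averaged responses). Under
noise this differs from log-then-average by a small convexity bias
($\approx \sigma^2\ln 10/2$ squared-units), which is part of the modelled
procedure, not an implementation accident.

The surface is the complete 4th-order polynomial in normalized coordinates
$k' = k/15$, $f' = f/66.6$, $l' = l/200$ (35 terms, graded-lexicographic
order, exponent triples serialized explicitly in the model JSON so files
are self-describing). Contrast is defined as modulation amplitude over
background level on the linear pixel scale; this convention is isolated in
one place so a luminance-Michelson variant can be substituted. Ridge
regression uses $\lambda = 0.001$ with the *intercept unpenalized*
(modified identity $I'$ with $I'(0,0)=0$): shrinking the constant term
would bias every sensitivity downward, while shrinking only the shape terms
merely stiffens the surface. Numerically the solve is implemented as an
augmented least-squares QR on $[X; \sqrt{\lambda}\,I']$ — algebraically
identical to $(X^\top X + \lambda I')^{-1}X^\top y$ but without squaring
the condition number, which matters because the polynomial basis on
$[0,1]^3$ is strongly collinear. At $\lambda = 0$ a rank check produces an
informative error instead of a silent pseudo-inverse.

The temporal slope analysis (`fit_log_linear_slope`) regresses
$\log_{10} s$ on $f$ for uniform-field records at one level. The linear
description is only valid over a band that depends on the adapting level,
so the band is an explicit argument (default 5–40 Hz) rather than a
constant; the published slope from the original data (−0.058/Hz against
Watson's −0.064) is not reproducible without those data and is not a test
target.

## The weighted-PSNR metric

`csf_weight_field()` evaluates the surface at each 2-D DFT bin's radial
frequency (converted to cycles/degree through the display geometry), at a
per-frame temporal frequency, and at the operating point — the pixel level
whose calibrated luminance is nearest 120 cd/m² for level-indexed surfaces,
or 120 cd/m² directly for luminance-indexed ones. Weights are normalized to
peak 1 (making scores scale-comparable with plain PSNR; the source does not
state its normalization) and the DC bin is forced to 1. The error image is
filtered by this weight via the convolution theorem and scored as
$10\log_{10}(255^2/\text{wMSE})$ with a 100 dB cap; the sequence score is
the per-frame mean. Filtering the *error* (rather than reference and
distorted separately) is one of two block orders consistent with the
description; the other can be added behind the same interface. The
per-frame temporal coefficient is likewise under-specified in the source;
we use $f_t = \text{fps}\cdot\text{gain}\cdot\overline{|F_t -
F_{t-1}|}/255$ (0 Hz for the first frame), monotone in motion energy,
cheap, and replaceable — or a fixed user-supplied frequency.

Metric-to-MOS mapping is the VQEG 4-parameter logistic fitted by `nls`
(port algorithm) with a deterministic data-driven initializer; correlation
is Pearson's $r$ with 95% Fisher-z bounds
($\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$). Both are the
standard VQA conventions, chosen because the source names neither.

## Numerical choices and degenerate inputs

* Kaiser window: base R `besselI`; tests check it against an independent
  power-series oracle.
* `0^0 = 1` in the polynomial basis, so the constant term is exact at the
  origin.
* Inputs beyond a model's normalizers are clamped with a warning (the
  surface is not trusted outside its calibrated range); negative inputs are
  errors.
* Identical frames give a 0/0-free capped score of 100 dB.
* `stopping_check` requires $n \ge 2$; zero-variance streams stop at
  $n = 2$.
* Model JSON round-trips at full double printing precision (~15
  significant digits), which is what "lossless" means here.
* PGM (P5/P2) replaces PNG throughout: no PNG codec exists in the
  supported dependency set, and PGM is losslessly convertible.

## Known limitations

* The generator emulates the *protocol*, not human psychophysics: no
  psychometric-function shape, no lapses or learning, no peripheral-vision
  effects, no chromatic channel.
* The published fitted coefficients and external-dataset PLCC table are not
  reproducible from the text; the package provides the machinery, not those
  numbers.
* The CLI renders static patterns only; it is not presentation software for
  human experiments, and no hardware PWM control is included.
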