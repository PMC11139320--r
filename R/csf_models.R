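# Contrast-sensitivity surfaces behind one pluggable interface: a 4th-order
# polynomial in normalized (spatial frequency, temporal frequency, background
# level), and the linear "pyramid of visibility" baseline in (k, f, log10 L).
# Both evaluate to log10 contrast sensitivity; sensitivity = 1 / threshold.

#' Exponent triples of the complete trivariate polynomial basis
#'
#' All (alpha, gamma, delta) with `alpha + gamma + delta <= order`, in graded
#' lexicographic order: ascending total degree, then ascending lexicographic
#' on (alpha, gamma, delta). The first triple is always (0, 0, 0), the
#' constant term. For order 4 there are choose(7, 3) = 35 triples.
#'
#' @param order maximum total degree (non-negative integer).
#' @return data frame with integer columns `alpha`, `gamma`, `delta`.
#' @export
polynomial_triples <- function(order = 4) {
  stopifnot(length(order) == 1, order >= 0, order == round(order))
  g <- expand.grid(delta = 0:order, gamma = 0:order, alpha = 0:order)
  g <- g[g$alpha + g$gamma + g$delta <= order, c("alpha", "gamma", "delta")]
  deg <- g$alpha + g$gamma + g$delta
  g <- g[base::order(deg, -g$alpha, -g$gamma, -g$delta), ]
  rownames(g) <- NULL
  g
}

#' Polynomial CSF surface
#'
#' Log10 contrast sensitivity modelled as a complete polynomial of total
#' degree `order` in the normalized variables `k' = k / k_max`,
#' `f' = f / f_max`, `l' = l / l_max`:
#' `log10(s) = sum c[alpha,gamma,delta] * k'^alpha * f'^gamma * l'^delta`.
#' The third variable is the 8-bit background pixel level, not luminance;
#' convert through a [display_model()] when a luminance-indexed surface is
#' needed. Normalizers default to the experimental maxima: 15 cycles/degree,
#' 66.6 Hz, background level 200.
#'
#' @param coefficients data frame with columns `alpha`, `gamma`, `delta`, `c`
#'   (log10-sensitivity scale). Triples must be unique and within `order`.
#'   Defaults to the all-zero coefficient set over the complete basis.
#' @param order maximum total degree.
#' @param k_max,f_max,l_max strictly positive normalizers.
#' @return an object of class `polynomial_csf` (also `csf_model`).
#' @export
polynomial_csf <- function(coefficients = NULL, order = 4, k_max = 15,
                           f_max = 66.6, l_max = 200) {
  stopifnot(k_max > 0, f_max > 0, l_max > 0)
  if (is.null(coefficients)) {
    coefficients <- polynomial_triples(order)
    coefficients$c <- 0
  }
  stopifnot(all(c("alpha", "gamma", "delta", "c") %in% names(coefficients)))
  if (any(coefficients$alpha + coefficients$gamma + coefficients$delta > order))
    stop("coefficient triple exceeds the model order")
  key <- paste(coefficients$alpha, coefficients$gamma, coefficients$delta)
  if (anyDuplicated(key)) stop("duplicate exponent triples")
  structure(list(order = order,
                 coefficients = coefficients[, c("alpha", "gamma", "delta", "c")],
                 k_max = k_max, f_max = f_max, l_max = l_max),
            class = c("polynomial_csf", "csf_model"))
}

#' Pyramid-of-visibility CSF surface
#'
#' The linear baseline `log10(s) = c0 + c_k * k + c_f * f + c_L * log10(L)`
#' with `k` in cycles/degree, `f` in Hz and `L` luminance in cd/m^2. Valid
#' away from low spatio-temporal frequencies; fitted slopes `c_k` and `c_f`
#' are expected non-positive (a warning, not an error, otherwise).
#'
#' @param c0 intercept on the log10-sensitivity scale.
#' @param c_f slope per Hz.
#' @param c_k slope per cycle/degree.
#' @param c_L slope per decade of luminance.
#' @return an object of class `pyramid_csf` (also `csf_model`).
#' @export
pyramid_csf <- function(c0, c_f, c_k, c_L) {
  if (c_f > 0 || c_k > 0)
    warning("c_f and c_k are expected non-positive for a fitted pyramid")
  structure(list(c0 = c0, c_f = c_f, c_k = c_k, c_L = c_L),
            class = c("pyramid_csf", "csf_model"))
}

#' Normalize polynomial-model inputs to the unit cube
#'
#' `k' = k/k_max`, `f' = f/f_max`, `l' = l/l_max`. Negative inputs are a
#' domain error; inputs beyond the normalizer are clamped to 1 with a
#' warning (the model is not trusted beyond its calibrated range).
#'
#' @param k,f,l spatial frequency (cpd), temporal frequency (Hz), 8-bit
#'   background level (vectorised, recycled to common length).
#' @param model a [polynomial_csf()].
#' @return list with components `kp`, `fp`, `lp`, each in \[0, 1\].
#' @export
csf_normalize_inputs <- function(k, f, l, model) {
  stopifnot(inherits(model, "polynomial_csf"))
  if (any(k < 0) || any(f < 0) || any(l < 0))
    stop("k, f and l must be non-negative")
  clamp <- function(x, xmax, nm) {
    if (any(x > xmax * (1 + 1e-9)))  # tolerance: log-spaced grids hit the max
      warning(nm, " above its normalizer (", xmax, "); clamped")
    pmin(x, xmax) / xmax
  }
  list(kp = clamp(k, model$k_max, "k"), fp = clamp(f, model$f_max, "f"),
       lp = clamp(l, model$l_max, "l"))
}

#' Polynomial basis row(s) at normalized inputs
#'
#' One column per exponent triple of [polynomial_triples()] in graded
#' lexicographic order; entry `k'^alpha * f'^gamma * l'^delta` with the
#' convention `0^0 = 1` (so the first column is the constant 1).
#'
#' @param kp,fp,lp normalized inputs in \[0, 1\] (vectorised, equal length).
#' @param order maximum total degree.
#' @return numeric matrix, one row per input point, `choose(order+3, 3)`
#'   columns.
#' @export
polynomial_terms <- function(kp, fp, lp, order = 4) {
  if (any(kp < 0 | kp > 1) || any(fp < 0 | fp > 1) || any(lp < 0 | lp > 1))
    stop("normalized inputs must lie in [0, 1]")
  tr <- polynomial_triples(order)
  n <- max(length(kp), length(fp), length(lp))
  kp <- rep_len(kp, n); fp <- rep_len(fp, n); lp <- rep_len(lp, n)
  X <- matrix(NA_real_, n, nrow(tr))
  pw <- function(x, e) if (e == 0) rep(1, length(x)) else x^e
  for (j in seq_len(nrow(tr)))
    X[, j] <- pw(kp, tr$alpha[j]) * pw(fp, tr$gamma[j]) * pw(lp, tr$delta[j])
  colnames(X) <- paste0("k", tr$alpha, "f", tr$gamma, "l", tr$delta)
  X
}

#' Log10 contrast sensitivity of a CSF surface
#'
#' @param model a `csf_model`.
#' @param k spatial frequency in cycles/degree.
#' @param f temporal frequency in Hz.
#' @param l for a [polynomial_csf()], the 8-bit background level; for a
#'   [pyramid_csf()], luminance in cd/m^2 (must be > 0).
#' @param ... passed to methods.
#' @return log10 sensitivity (vectorised).
#' @export
csf_log_sensitivity <- function(model, k, f, l, ...) {
  UseMethod("csf_log_sensitivity")
}

#' @export
csf_log_sensitivity.polynomial_csf <- function(model, k, f, l, ...) {
  z <- csf_normalize_inputs(k, f, l, model)
  X <- polynomial_terms(z$kp, z$fp, z$lp, model$order)
  tr <- polynomial_triples(model$order)
  key_basis <- paste(tr$alpha, tr$gamma, tr$delta)
  co <- model$coefficients
  cvec <- numeric(nrow(tr))
  cvec[match(paste(co$alpha, co$gamma, co$delta), key_basis)] <- co$c
  drop(X %*% cvec)
}

#' @export
csf_log_sensitivity.pyramid_csf <- function(model, k, f, l, ...) {
  if (any(l <= 0)) stop("pyramid CSF needs luminance L > 0")
  model$c0 + model$c_k * k + model$c_f * f + model$c_L * log10(l)
}

#' Evaluate a CSF surface
#'
#' @inheritParams csf_log_sensitivity
#' @return data frame with columns `log10_sensitivity`, `sensitivity`
#'   (`10^log10_sensitivity`) and `contrast_threshold` (`1/sensitivity`).
#' @export
evaluate_csf <- function(model, k, f, l) {
  ls <- csf_log_sensitivity(model, k, f, l)
  data.frame(log10_sensitivity = ls, sensitivity = 10^ls,
             contrast_threshold = 10^(-ls))
}

#' Serialize a CSF model to JSON
#'
#' Schema: `{"type": "polynomial"|"pyramid", "order", "normalizers":
#' {"k_max","f_max","l_max"}, "coefficients": [{"alpha","gamma","delta","c"}]}`
#' for polynomial models; `{"type": "pyramid", "coefficients": {"c0","c_f",
#' "c_k","c_L"}}` for the pyramid. Exponent triples are serialized
#' explicitly, so coefficient files are self-describing and order-independent
#' on read.
#'
#' @param model a `csf_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csf_json <- function(model, path) {
  obj <- if (inherits(model, "polynomial_csf")) {
    list(type = "polynomial", order = model$order,
         normalizers = list(k_max = model$k_max, f_max = model$f_max,
                            l_max = model$l_max),
         coefficients = model$coefficients)
  } else if (inherits(model, "pyramid_csf")) {
    list(type = "pyramid",
         coefficients = list(c0 = model$c0, c_f = model$c_f,
                             c_k = model$c_k, c_L = model$c_L))
  } else stop("not a csf_model")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CSF model from JSON
#'
#' @param path file written by [write_csf_json()] (or hand-authored to the
#'   same schema, e.g. an externally supplied surface).
#' @return a `csf_model`.
#' @export
read_csf_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "polynomial")) {
    polynomial_csf(coefficients = as.data.frame(obj$coefficients),
                   order = obj$order, k_max = obj$normalizers$k_max,
                   f_max = obj$normalizers$f_max, l_max = obj$normalizers$l_max)
  } else if (identical(obj$type, "pyramid")) {
    co <- obj$coefficients
    suppressWarnings(pyramid_csf(co$c0, co$c_f, co$c_k, co$c_L))
  } else stop("unknown CSF model type: ", obj$type)
}

#' @export
print.polynomial_csf <- function(x, ...) {
  cat("Polynomial CSF surface, order", x$order, "(",
      nrow(x$coefficients), "terms )\n")
  cat("  normalizers: k_max =", x$k_max, "cpd, f_max =", x$f_max,
      "Hz, l_max =", x$l_max, "\n")
  invisible(x)
}

#' @export
print.pyramid_csf <- function(x, ...) {
  cat(sprintf("Pyramid of visibility: log10 s = %.4g + %.4g k + %.4g f + %.4g log10 L\n",
              x$c0, x$c_k, x$c_f, x$c_L))
  invisible(x)
}
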