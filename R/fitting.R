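# From threshold tables to CSF surfaces: anomalous-condition exclusion,
# BT.500-style confidence statistics and the sequential stopping rule,
# condition aggregation, ridge regression with an unpenalized intercept, and
# the linear slope analysis of the uniform-flicker experiment.
#
# Contrast convention (isolated here): threshold_contrast is the modulation
# amplitude divided by the background level on the linear pixel scale
# (Weber-style on pixel values); sensitivity s = 1 / threshold_contrast.

THRESHOLD_COLUMNS <- c("participant_id", "stage", "spatial_frequency",
                       "temporal_frequency", "background_level",
                       "threshold_contrast", "replicate_index")

#' Default exclusion list of anomalous flicker conditions
#'
#' (temporal frequency Hz, background level) pairs at which observers
#' reported spurious flicker attributable to the display/PWM hardware rather
#' than vision, excluded from analysis by default: 15 and 40 Hz at level 200;
#' 36 Hz at level 160; 13, 20 and 48 Hz at level 80; 40 and 46 Hz at level
#' 40. User-overridable.
#'
#' @return data frame with columns `temporal_frequency`, `background_level`.
#' @export
default_exclusions <- function() {
  data.frame(
    temporal_frequency = c(15, 40, 36, 13, 20, 48, 40, 46),
    background_level   = c(200, 200, 160, 80, 80, 80, 40, 40))
}

#' Remove excluded (temporal frequency, background level) conditions
#'
#' @param records threshold table (see [read_thresholds()] for the schema).
#' @param exclusions data frame of pairs as from [default_exclusions()];
#'   `NULL` or zero rows means no filtering.
#' @return list with `records` (filtered table) and `removed` (row count).
#' @export
apply_exclusions <- function(records, exclusions = default_exclusions()) {
  if (is.null(exclusions) || nrow(exclusions) == 0)
    return(list(records = records, removed = 0L))
  key <- paste(records$temporal_frequency, records$background_level)
  bad <- key %in% paste(exclusions$temporal_frequency,
                        exclusions$background_level)
  list(records = records[!bad, , drop = FALSE], removed = sum(bad))
}

#' BT.500-style 95% confidence statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and the 95%
#' confidence half-width `1.96 * sd / sqrt(n)` (normal quantile, per the
#' BT.500 formula, rather than a small-sample t quantile).
#'
#' @param samples numeric vector, length >= 2.
#' @return list with `mean`, `sd`, `ci_halfwidth`, `n`.
#' @export
bt500_ci <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("confidence interval undefined for n < 2")
  m <- mean(samples)
  s <- stats::sd(samples)
  list(mean = m, sd = s, ci_halfwidth = 1.96 * s / sqrt(n), n = n)
}

#' Sequential stopping rule on the confidence interval
#'
#' Measurement of a condition stops once the 95% confidence half-width falls
#' below 5% of the current mean; each (f, l, k) condition is evaluated
#' independently of every other.
#'
#' @param samples thresholds accumulated so far (length >= 2).
#' @return `TRUE` to stop, `FALSE` to continue measuring.
#' @export
stopping_check <- function(samples) {
  ci <- bt500_ci(samples)
  ci$ci_halfwidth < 0.05 * ci$mean
}

#' Aggregate threshold records into per-condition summaries
#'
#' Thresholds are averaged within each (spatial frequency, temporal
#' frequency, background level) condition across participants, stages and
#' replicates first; the log10 sensitivity of the condition is then the log
#' of the inverse of that averaged threshold (average-then-log: the response
#' vector fitted downstream is the logarithm of the average responses).
#'
#' @param records threshold table.
#' @return data frame with columns `spatial_frequency`, `temporal_frequency`,
#'   `background_level`, `mean_threshold`, `n`, `log10_sensitivity`.
#' @export
aggregate_conditions <- function(records) {
  if (nrow(records) == 0) stop("no records to aggregate")
  agg <- stats::aggregate(
    threshold_contrast ~ spatial_frequency + temporal_frequency +
      background_level,
    data = records, FUN = mean)
  cnt <- stats::aggregate(
    threshold_contrast ~ spatial_frequency + temporal_frequency +
      background_level,
    data = records, FUN = length)
  out <- agg
  names(out)[names(out) == "threshold_contrast"] <- "mean_threshold"
  out$n <- cnt$threshold_contrast
  out$log10_sensitivity <- log10(1 / out$mean_threshold)
  out <- out[base::order(out$spatial_frequency, out$temporal_frequency,
                         out$background_level), ]
  rownames(out) <- NULL
  out
}

#' Ridge regression of the polynomial CSF surface
#'
#' Solves `c = (X'X + lambda * I')^{-1} X'y` where `X` holds the polynomial
#' basis at the normalized condition coordinates, `y` the per-condition log10
#' sensitivities, and `I'` is the identity with its constant-term diagonal
#' entry zeroed so the intercept is unpenalized. With `lambda = 0` this is
#' ordinary least squares and requires a full-rank design (an informative
#' rank-deficiency error otherwise). Deterministic.
#'
#' @param conditions output of [aggregate_conditions()].
#' @param lambda ridge regularization coefficient (>= 0; default 0.001).
#' @param template a [polynomial_csf()] supplying order and normalizers.
#' @return the fitted `polynomial_csf`.
#' @export
ridge_fit <- function(conditions, lambda = 0.001, template = polynomial_csf()) {
  stopifnot(inherits(template, "polynomial_csf"), lambda >= 0)
  z <- csf_normalize_inputs(conditions$spatial_frequency,
                            conditions$temporal_frequency,
                            conditions$background_level, template)
  X <- polynomial_terms(z$kp, z$fp, z$lp, template$order)
  y <- conditions$log10_sensitivity
  p <- ncol(X)
  if (lambda == 0 && qr(X)$rank < p)
    stop("rank-deficient design: ", nrow(X), " conditions span rank ",
         qr(X)$rank, " < ", p, " basis terms; increase conditions or lambda")
  # solved as an augmented least-squares problem [X; sqrt(lambda) I'] --
  # algebraically identical to (X'X + lambda I')^{-1} X'y but without
  # squaring the condition number of X
  Ip <- diag(p)
  Ip[1, 1] <- 0  # intercept unpenalized
  cvec <- qr.coef(qr(rbind(X, sqrt(lambda) * Ip)), c(y, numeric(p)))
  co <- polynomial_triples(template$order)
  co$c <- drop(cvec)
  polynomial_csf(co, order = template$order, k_max = template$k_max,
                 f_max = template$f_max, l_max = template$l_max)
}

#' Linear slope of log10 sensitivity against temporal frequency
#'
#' Ordinary least squares of log10 sensitivity on temporal frequency for
#' uniform-field flicker records (`spatial_frequency == 0`) at one background
#' level, restricted to an explicit frequency range: the linear (pyramid)
#' description only holds over a limited band, and the band of good fit
#' depends on the adapting level, so the range is an argument rather than a
#' constant.
#'
#' @param records threshold table.
#' @param background_level level whose records are fitted.
#' @param frequency_range length-2 numeric, inclusive Hz bounds.
#' @return list with `slope` (per Hz), `intercept`, `n`.
#' @export
fit_log_linear_slope <- function(records, background_level,
                                 frequency_range = c(5, 40)) {
  stopifnot(length(frequency_range) == 2)
  sub <- records[records$spatial_frequency == 0 &
                   records$background_level == background_level &
                   records$temporal_frequency >= frequency_range[1] &
                   records$temporal_frequency <= frequency_range[2], ]
  if (length(unique(sub$temporal_frequency)) < 2)
    stop("need >= 2 distinct temporal frequencies within frequency_range")
  y <- log10(1 / sub$threshold_contrast)
  fit <- stats::lm(y ~ sub$temporal_frequency)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = nrow(sub))
}

#' Read / write threshold tables
#'
#' CSV schema (header required, UTF-8, '.' decimal): `participant_id`,
#' `stage` (`flicker` or `pattern`), `spatial_frequency` (cycles/degree; 0
#' for uniform-field flicker), `temporal_frequency` (Hz), `background_level`
#' (8-bit), `threshold_contrast` (Michelson amplitude/level, in (0, 1]),
#' `replicate_index`.
#'
#' @param path CSV file path.
#' @return `read_thresholds`: the validated data frame.
#' @export
read_thresholds <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_thresholds(records)
  records
}

#' @param records threshold table to write.
#' @rdname read_thresholds
#' @return `write_thresholds`: `path`, invisibly.
#' @export
write_thresholds <- function(records, path) {
  validate_thresholds(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_thresholds <- function(records) {
  missing_cols <- setdiff(THRESHOLD_COLUMNS, names(records))
  if (length(missing_cols))
    stop("threshold table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(records$threshold_contrast <= 0 | records$threshold_contrast > 1))
    stop("threshold_contrast must lie in (0, 1]")
  if (any(records$spatial_frequency < 0) || any(records$temporal_frequency < 0))
    stop("frequencies must be >= 0")
  invisible(records)
}
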