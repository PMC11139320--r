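# Synthetic-observer engine: reproduces the two threshold-experiment designs
# (uniform-field flicker; spatio-temporal Mira pattern) and generates
# plausible threshold tables from a ground-truth CSF with lognormal
# within-observer scatter, so the whole fitting pipeline is testable without
# any human data.

#' Factorial design of the two threshold experiments
#'
#' Experiment 1 (temporal contrast sensitivity): uniform-field flicker at 12
#' temporal frequencies x 5 background levels, 13 participants, one
#' measurement stage -- 60 conditions per participant, 780 in total.
#' Experiment 2 (spatio-temporal): 8 spatial x 12 temporal frequencies x 5
#' levels, 29 participants, two adjustment stages per condition (flicker
#' visibility first, then pattern visibility) -- 960 threshold evaluations
#' per participant, 27840 in total.
#'
#' The individual frequency values are configurable; defaults are log-spaced
#' within the experimental extremes (1--66.6 Hz temporal, 0.5--15
#' cycles/degree spatial). Flicker-stage rows record spatial frequency 0
#' (uniform field).
#'
#' @param experiment 1 or 2.
#' @param temporal_frequencies 12 temporal frequencies in Hz.
#' @param spatial_frequencies 8 spatial frequencies in cycles/degree
#'   (Experiment 2 only).
#' @param background_levels 8-bit background levels.
#' @param n_participants number of observers (defaults: 13 for Experiment 1,
#'   29 for Experiment 2).
#' @return data frame with columns `participant_id`, `stage`,
#'   `spatial_frequency`, `temporal_frequency`, `background_level`.
#' @export
build_design <- function(experiment,
                         temporal_frequencies = 10^seq(log10(1), log10(66.6),
                                                       length.out = 12),
                         spatial_frequencies = 10^seq(log10(0.5), log10(15),
                                                      length.out = 8),
                         background_levels = c(40, 80, 120, 160, 200),
                         n_participants = if (experiment == 1) 13 else 29) {
  stopifnot(experiment %in% c(1, 2))
  if (any(background_levels < 0 | background_levels > 255))
    stop("background levels must be 8-bit values")
  if (experiment == 1) {
    if (length(temporal_frequencies) != 12)
      warning("Experiment 1 as published uses 12 temporal frequencies")
    per <- expand.grid(background_level = background_levels,
                       temporal_frequency = temporal_frequencies)
    per$spatial_frequency <- 0
    per$stage <- "flicker"
  } else {
    if (length(temporal_frequencies) != 12 || length(spatial_frequencies) != 8)
      warning("Experiment 2 as published uses 8 spatial x 12 temporal frequencies")
    grid <- expand.grid(background_level = background_levels,
                        temporal_frequency = temporal_frequencies,
                        spatial_frequency = spatial_frequencies)
    per <- rbind(transform(grid, stage = "flicker"),
                 transform(grid, stage = "pattern"))
    # the flicker-visibility stage is a uniform-field measurement
    per$spatial_frequency[per$stage == "flicker"] <- 0
  }
  out <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    cbind(participant_id = sprintf("P%02d", p), per)
  }))
  out <- out[, c("participant_id", "stage", "spatial_frequency",
                 "temporal_frequency", "background_level")]
  rownames(out) <- NULL
  out
}

#' Synthetic observer model
#'
#' Thresholds are generated as `(1 / s_true) * 10^(eps + b)` with
#' `eps ~ N(0, log10_noise_sd)` independently per trial and `b` a fixed
#' per-observer offset drawn once per observer from
#' `N(0, observer_bias_sd)`, then clipped to the measurable unit interval
#' (0, 1]. The lognormal form makes the median threshold equal the true
#' threshold.
#'
#' @param true_csf ground-truth `csf_model`. A [pyramid_csf()] truth is
#'   indexed by luminance, so background levels are converted through
#'   `display`; a [polynomial_csf()] truth is indexed by the level directly.
#' @param log10_noise_sd within-observer scatter of log10 threshold
#'   (default 0.05).
#' @param observer_bias_sd between-observer log10 offset scatter
#'   (default 0; see the methods vignette for why the default is unbiased).
#' @param display a [display_model()] used for level -> luminance conversion.
#' @return an object of class `observer_model`.
#' @export
observer_model <- function(true_csf, log10_noise_sd = 0.05,
                           observer_bias_sd = 0, display = display_model()) {
  stopifnot(inherits(true_csf, "csf_model"),
            log10_noise_sd >= 0, observer_bias_sd >= 0)
  structure(list(true_csf = true_csf, log10_noise_sd = log10_noise_sd,
                 observer_bias_sd = observer_bias_sd, display = display),
            class = "observer_model")
}

#' True log10 sensitivity of an observer model at design coordinates
#'
#' @param obs an [observer_model()].
#' @param k spatial frequency (cycles/degree).
#' @param f temporal frequency (Hz).
#' @param l 8-bit background level (converted to luminance for a pyramid
#'   truth).
#' @return log10 sensitivity (vectorised).
#' @export
true_log10_sensitivity <- function(obs, k, f, l) {
  stopifnot(inherits(obs, "observer_model"))
  if (inherits(obs$true_csf, "pyramid_csf")) {
    csf_log_sensitivity(obs$true_csf, k, f, pixel_to_luminance(l, obs$display))
  } else {
    csf_log_sensitivity(obs$true_csf, k, f, l)
  }
}

#' Simulate threshold measurements at one condition
#'
#' Draws from the observer noise model around the ground-truth threshold.
#' Uses the current RNG state; seed it with `set.seed()` (or use
#' [simulate_session()], which manages per-observer streams).
#'
#' @param obs an [observer_model()].
#' @param k,f,l condition coordinates (see [true_log10_sensitivity()]).
#' @param n number of independent draws.
#' @param bias fixed observer offset `b` on the log10 scale (default 0).
#' @return numeric vector of `n` threshold contrasts in (0, 1].
#' @export
simulate_threshold <- function(obs, k, f, l, n = 1, bias = 0) {
  stopifnot(inherits(obs, "observer_model"))
  t0 <- 10^(-true_log10_sensitivity(obs, k, f, l))
  eps <- if (obs$log10_noise_sd > 0) stats::rnorm(n, 0, obs$log10_noise_sd)
         else numeric(n)
  pmin(t0 * 10^(eps + bias), 1)
}

# Deterministic per-observer seed derived from the master seed and the
# participant label (FNV-1a), so any participant subset is reproducible
# independently of which other observers are simulated.
observer_seed <- function(master_seed, participant_id) {
  h <- fnv1a_hash(paste0(master_seed, "/", participant_id))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Simulate a full measurement session
#'
#' Runs every observer through the design. With `stopping = "off"` exactly
#' one record is produced per design row. With `stopping = "on"` each
#' (observer, condition) accrues replicates (minimum 2) until the BT.500
#' stopping rule [stopping_check()] passes or `max_replicates` is reached
#' (the condition is then flagged in the `stopped` column).
#'
#' All randomness derives from `seed` through a fixed per-observer splitting
#' rule: the same seed yields a bit-identical table.
#'
#' @param obs an [observer_model()].
#' @param design a [build_design()] table.
#' @param stopping `"off"` or `"on"`.
#' @param max_replicates replicate cap per condition when stopping is on
#'   (>= 2).
#' @param seed master integer seed.
#' @return threshold table in the [read_thresholds()] schema (plus a
#'   `stopped` logical column when stopping is on).
#' @export
simulate_session <- function(obs, design, stopping = c("off", "on"),
                             max_replicates = 50, seed = 1) {
  stopping <- match.arg(stopping)
  stopifnot(inherits(obs, "observer_model"))
  if (stopping == "on" && max_replicates < 2)
    stop("max_replicates must be >= 2 when stopping is on")
  participants <- unique(design$participant_id)
  chunks <- vector("list", length(participants))
  for (i in seq_along(participants)) {
    pid <- participants[i]
    rows <- design[design$participant_id == pid, , drop = FALSE]
    set.seed(observer_seed(seed, pid))
    bias <- if (obs$observer_bias_sd > 0)
      stats::rnorm(1, 0, obs$observer_bias_sd) else 0
    t0 <- 10^(-true_log10_sensitivity(obs, rows$spatial_frequency,
                                      rows$temporal_frequency,
                                      rows$background_level))
    if (stopping == "off") {
      eps <- if (obs$log10_noise_sd > 0)
        stats::rnorm(nrow(rows), 0, obs$log10_noise_sd) else numeric(nrow(rows))
      chunk <- rows
      chunk$threshold_contrast <- pmin(t0 * 10^(eps + bias), 1)
      chunk$replicate_index <- 1L
      chunks[[i]] <- chunk
    } else {
      per_row <- vector("list", nrow(rows))
      for (j in seq_len(nrow(rows))) {
        eps <- if (obs$log10_noise_sd > 0)
          stats::rnorm(max_replicates, 0, obs$log10_noise_sd)
          else numeric(max_replicates)
        th <- pmin(t0[j] * 10^(eps + bias), 1)
        n_stop <- max_replicates
        stopped <- FALSE
        for (n in 2:max_replicates) {
          if (stopping_check(th[1:n])) { n_stop <- n; stopped <- TRUE; break }
        }
        chunk <- rows[rep(j, n_stop), , drop = FALSE]
        chunk$threshold_contrast <- th[1:n_stop]
        chunk$replicate_index <- seq_len(n_stop)
        chunk$stopped <- stopped
        per_row[[j]] <- chunk
      }
      chunks[[i]] <- do.call(rbind, per_row)
    }
  }
  out <- do.call(rbind, chunks)
  cols <- c(THRESHOLD_COLUMNS, intersect("stopped", names(out)))
  out <- out[, cols]
  rownames(out) <- NULL
  out
}
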