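make_records <- function(k, f, l, th, pid = "P01", stage = "pattern") {
  data.frame(participant_id = pid, stage = stage, spatial_frequency = k,
             temporal_frequency = f, background_level = l,
             threshold_contrast = th, replicate_index = 1L)
}

test_that("exclusion filtering removes exactly the listed condition pairs", {
  # empty list is the identity
  rec <- make_records(1, c(15, 40, 25), c(200, 120, 80), 0.01)
  expect_identical(apply_exclusions(rec, NULL)$records, rec)
  expect_equal(apply_exclusions(rec, data.frame(temporal_frequency = numeric(0),
                                                background_level = numeric(0)))$removed,
               0L)
  # (40 Hz, level 120) is retained: 120 is not a listed level
  out <- apply_exclusions(make_records(1, 40, 120, 0.01))
  expect_equal(nrow(out$records), 1)
  expect_equal(out$removed, 0L)
  # the 8 listed pairs remove exactly 8 spatial conditions each from a
  # full spatio-temporal grid that contains the anomalous frequencies
  grid <- expand.grid(spatial_frequency = 1:8,
                      temporal_frequency = c(13, 15, 20, 36, 40, 46, 48, 60),
                      background_level = c(40, 80, 120, 160, 200))
  rec <- make_records(grid$spatial_frequency, grid$temporal_frequency,
                      grid$background_level, 0.01)
  out <- apply_exclusions(rec)
  # brute-force oracle: scan the grid against the printed pairs
  excl <- default_exclusions()
  oracle <- sum(vapply(seq_len(nrow(rec)), function(i) {
    any(excl$temporal_frequency == rec$temporal_frequency[i] &
          excl$background_level == rec$background_level[i])
  }, logical(1)))
  expect_equal(out$removed, oracle)
  expect_equal(out$removed, 8L * 8L)
  expect_equal(nrow(out$records) + out$removed, nrow(rec))
})

test_that("BT.500 confidence statistics match hand computation", {
  ci <- bt500_ci(c(1, 2, 3))
  expect_equal(ci$mean, 2)
  expect_equal(ci$sd, 1)
  expect_equal(ci$ci_halfwidth, 1.96 / sqrt(3))
  expect_equal(bt500_ci(rep(0.4, 5))$ci_halfwidth, 0)
  # 1/sqrt(n) scaling for replicated data
  x <- c(1, 2, 3, 2, 1.5)
  expect_equal(bt500_ci(rep(x, 4))$ci_halfwidth,
               bt500_ci(x)$ci_halfwidth / 2 * sqrt(sd(rep(x, 4))^2 / sd(x)^2) * 1,
               tolerance = 0.05)
  expect_error(bt500_ci(1), "n < 2")
})

test_that("stopping rule straddles the 5%-of-mean criterion", {
  expect_true(stopping_check(c(0.5, 0.5)))
  # mean 1, halfwidth just below / above 0.05
  make <- function(target_half) {
    s <- target_half * sqrt(2) / 1.96
    c(1 - s / sqrt(2), 1 + s / sqrt(2))
  }
  expect_true(stopping_check(make(0.049)))
  expect_false(stopping_check(make(0.051)))
})

test_that("stopping matches a brute-force sequential scan on noisy streams", {
  set.seed(99)
  for (rep in 1:25) {
    stream <- 0.02 * 10^rnorm(60, 0, 0.05)
    # oracle: explicit sequential replay with direct formulas
    oracle_n <- NA
    for (n in 2:60) {
      m <- mean(stream[1:n]); s <- sd(stream[1:n])
      if (1.96 * s / sqrt(n) < 0.05 * m) { oracle_n <- n; break }
    }
    pkg_n <- NA
    for (n in 2:60) if (stopping_check(stream[1:n])) { pkg_n <- n; break }
    expect_equal(pkg_n, oracle_n)
  }
})

test_that("aggregation averages thresholds before taking logs", {
  one <- make_records(2, 10, 120, 0.04)
  agg <- aggregate_conditions(one)
  expect_equal(agg$log10_sensitivity, log10(1 / 0.04))
  two <- make_records(c(2, 2), c(10, 10), c(120, 120), c(0.01, 0.03),
                      pid = c("P01", "P02"))
  agg <- aggregate_conditions(two)
  expect_equal(agg$mean_threshold, 0.02)
  expect_equal(agg$log10_sensitivity, log10(50))
  expect_equal(agg$n, 2)
  # order and participant labels do not matter
  shuffled <- two[2:1, ]
  shuffled$participant_id <- c("Z9", "A1")
  expect_equal(aggregate_conditions(shuffled), agg)
})

test_that("ridge with lambda = 0 equals an independent QR least-squares solve", {
  set.seed(21)
  grid <- expand.grid(k = c(0, 4, 8, 12, 15), f = c(0, 16, 33, 50, 66.6),
                      l = c(40, 80, 120, 160, 200))
  y <- rnorm(nrow(grid))
  cond <- data.frame(spatial_frequency = grid$k, temporal_frequency = grid$f,
                     background_level = grid$l,
                     mean_threshold = 10^(-y), n = 1, log10_sensitivity = y)
  fit <- ridge_fit(cond, lambda = 0)
  # oracle: QR decomposition (different algorithm from the normal equations)
  tmpl <- polynomial_csf()
  z <- csf_normalize_inputs(grid$k, grid$f, grid$l, tmpl)
  X <- polynomial_terms(z$kp, z$fp, z$lp, 4)
  expect_equal(fit$coefficients$c, unname(qr.coef(qr(X), y)),
               tolerance = 1e-10)
})

test_that("the intercept is unpenalized: intercept-only ridge returns the mean", {
  y <- c(1.1, 1.9, 3.2, 0.4)
  cond <- data.frame(spatial_frequency = 0, temporal_frequency = 0,
                     background_level = 0, mean_threshold = 10^(-y), n = 1,
                     log10_sensitivity = y)
  # order 0: the single basis column is the constant
  fit <- ridge_fit(cond, lambda = 10, template = polynomial_csf(order = 0))
  expect_equal(fit$coefficients$c, mean(y), tolerance = 1e-12)
})

test_that("exact quartic data are recovered with lambda = 0", {
  set.seed(33)
  co <- polynomial_triples(4)
  co$c <- rnorm(35, sd = 0.3)
  truth <- polynomial_csf(co)
  grid <- expand.grid(k = c(0, 4, 8, 12, 15), f = c(0, 16, 33, 50, 66.6),
                      l = c(40, 80, 120, 160, 200))
  y <- csf_log_sensitivity(truth, grid$k, grid$f, grid$l)
  cond <- data.frame(spatial_frequency = grid$k, temporal_frequency = grid$f,
                     background_level = grid$l, mean_threshold = 10^(-y),
                     n = 1, log10_sensitivity = y)
  fit <- ridge_fit(cond, lambda = 0)
  expect_equal(fit$coefficients$c, co$c, tolerance = 1e-8)
})

test_that("ridge shrinkage is continuous and monotone in lambda", {
  set.seed(5)
  grid <- expand.grid(k = c(0, 4, 8, 12, 15), f = c(0, 16, 33, 50, 66.6),
                      l = c(40, 80, 120, 160, 200))
  # smooth quartic signal plus modest noise, so coefficients are tame
  co <- polynomial_triples(4); co$c <- rnorm(35, sd = 0.3)
  truth <- polynomial_csf(co)
  y <- csf_log_sensitivity(truth, grid$k, grid$f, grid$l) +
    rnorm(nrow(grid), sd = 0.02)
  cond <- data.frame(spatial_frequency = grid$k, temporal_frequency = grid$f,
                     background_level = grid$l, mean_threshold = 10^(-y),
                     n = 1, log10_sensitivity = y)
  norms <- vapply(c(0, 1e-10, 1e-3, 1e-2, 1e-1, 1), function(lam) {
    sqrt(sum(ridge_fit(cond, lambda = lam)$coefficients$c[-1]^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # continuity at lambda -> 0 (the basis is collinear, so the norm drops
  # steeply with lambda; continuity is a limit statement)
  expect_equal(norms[1], norms[2], tolerance = 1e-4)
  # rank deficiency at lambda = 0 is reported informatively
  expect_error(ridge_fit(cond[1:10, ], lambda = 0), "rank-deficient")
})

test_that("slope analysis recovers a pyramid temporal slope exactly without noise", {
  dm <- display_model()
  truth <- pyramid_csf(2.5, -0.064, -0.04, 0.3)
  f <- seq(5, 40, length.out = 8)
  th <- 10^(-csf_log_sensitivity(truth, 0, f, pixel_to_luminance(120, dm)))
  rec <- make_records(0, f, 120, th, stage = "flicker")
  fit <- fit_log_linear_slope(rec, 120, c(5, 40))
  expect_equal(fit$slope, -0.064, tolerance = 1e-9)
  # adding a frequency-independent offset changes the intercept only
  rec2 <- rec; rec2$threshold_contrast <- rec$threshold_contrast * 10^(-0.5)
  fit2 <- fit_log_linear_slope(rec2, 120, c(5, 40))
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
  expect_equal(fit2$intercept - fit$intercept, 0.5, tolerance = 1e-9)
  # the range argument restricts the fit
  expect_error(fit_log_linear_slope(rec, 120, c(41, 60)), "distinct")
})

test_that("noisy slope estimates stay within 3 standard errors (Monte Carlo)", {
  dm <- display_model()
  truth <- pyramid_csf(2.5, -0.058, -0.04, 0.3)
  f <- rep(seq(5, 40, length.out = 8), each = 5)
  t0 <- 10^(-csf_log_sensitivity(truth, 0, f, pixel_to_luminance(120, dm)))
  set.seed(8)
  hits <- vapply(1:200, function(i) {
    th <- pmin(t0 * 10^(rnorm(length(f), 0, 0.05)), 1)
    rec <- make_records(0, f, 120, th, stage = "flicker")
    fit <- fit_log_linear_slope(rec, 120, c(5, 40))
    y <- log10(1 / th)
    se <- summary(lm(y ~ f))$coefficients[2, 2]
    abs(fit$slope - (-0.058)) < 3 * se
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("threshold CSV round-trips through the schema unchanged", {
  rec <- make_records(c(0, 2), c(10, 20), c(120, 80), c(0.02, 0.05),
                      pid = c("P01", "P02"), stage = c("flicker", "pattern"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thresholds(rec, path)
  back <- read_thresholds(path)
  expect_equal(back, rec)
  bad <- rec; bad$threshold_contrast[1] <- 1.5
  expect_error(write_thresholds(bad, path), "\\(0, 1\\]")
  suppressWarnings(
    expect_error(read_thresholds(withr::local_tempfile(fileext = ".csv"))))
})
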