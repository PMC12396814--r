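test_that("isosbestic fit recovers exact affine relations", {
  ch405 <- c(1, 2, 3)
  fitted <- fit_isosbestic(ch405, 2 * ch405)
  expect_equal(attr(fitted, "a"), 2)
  expect_equal(attr(fitted, "c"), 0)
  expect_equal(as.numeric(fitted), c(2, 4, 6))

  # perfect fit reproduces the 470 channel
  f2 <- fit_isosbestic(ch405, 3 * ch405 + 1)
  expect_equal(as.numeric(f2), 3 * ch405 + 1)

  expect_error(fit_isosbestic(rep(1, 10), rnorm(10)), "constant")

  # coefficient recovery from noisy proportional channels
  set.seed(2)
  x <- runif(2000, 1, 2)
  y <- 1.5 * x + 0.2 + rnorm(2000, 0, 0.01)
  f3 <- fit_isosbestic(x, y)
  se_a <- 0.01 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(attr(f3, "a") - 1.5), 4 * se_a)
})

test_that("dF/F follows the percentage formula and its invariances", {
  expect_equal(compute_dff(11, 10), 10)
  expect_equal(compute_dff(rep(5, 4), rep(5, 4)), rep(0, 4))
  expect_error(compute_dff(c(1, 2), c(1, -1)), "index 2")

  # scaling both raw channels leaves dF/F unchanged
  set.seed(4)
  ch405 <- runif(500, 1, 2)
  ch470 <- 1.3 * ch405 + 0.1 + rnorm(500, 0, 0.05)
  dff1 <- compute_dff(ch470, fit_isosbestic(ch405, ch470))
  k <- 7.3
  dff2 <- compute_dff(k * ch470, fit_isosbestic(k * ch405, k * ch470))
  expect_equal(dff1, dff2, tolerance = 1e-10)

  # exact affine 470 of 405 gives identically zero dF/F
  ch470b <- 2.2 * ch405 + 0.4
  expect_equal(compute_dff(ch470b, fit_isosbestic(ch405, ch470b)),
               rep(0, 500), tolerance = 1e-10)
})

test_that("event alignment bins on a half-open window", {
  tr <- trace_from_fun(function(t) rep(2, length(t)), t_max = 10)
  out <- event_aligned_matrix(tr, c(3, 5, 7), window = c(-1, 1), bin_s = 1)
  expect_equal(dim(out$matrix), c(3, 2))
  expect_equal(out$psth, c(2, 2))

  # impulse at the event lands in the bin containing time zero
  imp <- trace_from_fun(function(t) as.numeric(abs(t - 5) < 0.004), t_max = 10)
  out2 <- event_aligned_matrix(imp, 5, window = c(-1, 1), bin_s = 0.5)
  expect_equal(which.max(out2$psth), 3)  # bin [0, 0.5)

  expect_error(event_aligned_matrix(tr, numeric(0), c(-1, 1), 1), "empty")
})

test_that("onset peak subtracts the pre-event baseline", {
  tr <- trace_from_fun(function(t) ifelse(t >= 5 & t < 5.5, 5, 1), t_max = 10)
  expect_equal(onset_peak_response(tr, 5), 4)
  flat <- trace_from_fun(function(t) rep(3, length(t)), t_max = 10)
  expect_equal(onset_peak_response(flat, 5), 0)
  expect_warning(out <- onset_peak_response(flat, 0.2), "dropped")
  expect_true(is.na(out))
})

test_that("time-domain slopes are exact on linear input and unbiased on noise", {
  tr <- trace_from_fun(function(t) 0.5 * (t - 2), t_max = 20)
  expect_equal(ramp_slope_time(tr, 2), 0.5, tolerance = 1e-10)
  flat <- trace_from_fun(function(t) rep(1, length(t)), t_max = 20)
  expect_equal(ramp_slope_time(flat, 2), 0)
  expect_warning(out <- ramp_slope_time(flat, 15), "dropped")
  expect_true(is.na(out))

  # noisy linear ramp recovered within 3 analytic OLS standard errors
  set.seed(6)
  fs <- 120; sig <- 0.3
  tt <- seq(0, 20, by = 1 / fs)
  sel <- tt >= 5 & tt < 10
  se <- sig / sqrt(sum((tt[sel] - mean(tt[sel]))^2))
  hits <- vapply(1:100, function(i) {
    tr2 <- dff_trace(tt, 0.4 * (tt - 2) + rnorm(length(tt), 0, sig))
    abs(ramp_slope_time(tr2, 2) - 0.4) < 3 * se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pre-cue slope uses the window before onset", {
  tr <- trace_from_fun(function(t) ifelse(t < 5, 0.3 * t, 1.5), t_max = 10)
  expect_equal(pre_cue_slope(tr, 5, 2), 0.3, tolerance = 1e-10)
  flat <- trace_from_fun(function(t) rep(1, length(t)), t_max = 10)
  expect_equal(pre_cue_slope(flat, 5, 2), 0)
})

test_that("distance alignment averages triplets and drops repeats", {
  out <- distance_align(1:9, c(5.0, 5.0, 5.2))
  expect_equal(out$distance_cm, c(5.0, 5.2))
  expect_equal(out$dff_percent, c(2, 8))

  out2 <- distance_align(1:9, c(1, 2, 3))
  expect_equal(nrow(out2), 3)                      # strictly increasing: keep all

  out3 <- distance_align(rep(1, 9), c(4, 4, 4))
  expect_equal(nrow(out3), 1)                      # stationary animal

  expect_error(distance_align(1:20, c(1, 2, 3)), "3:1")
})

test_that("distance-domain slope and per-cm binning", {
  pairs <- data.frame(distance_cm = seq(0, 67, by = 0.5))
  pairs$dff_percent <- 0.1 * pairs$distance_cm
  expect_equal(ramp_slope_distance(pairs), 0.1, tolerance = 1e-10)
  pairs$dff_percent <- 1
  expect_equal(ramp_slope_distance(pairs), 0)
  expect_warning(out <- ramp_slope_distance(pairs[pairs$distance_cm < 20, ]),
                 "dropped")
  expect_true(is.na(out))

  b <- bin_by_cm(data.frame(distance_cm = c(4.6, 5.4),
                            dff_percent = c(1, 3)))
  expect_equal(b$dff_percent[b$distance_cm == 5], 2)
  expect_true(all(is.na(b$dff_percent[b$distance_cm > 6])))

  ident <- bin_by_cm(data.frame(distance_cm = 0:67, dff_percent = 0:67))
  expect_equal(ident$dff_percent, as.numeric(0:67))

  unif <- bin_by_cm(data.frame(distance_cm = runif(100, 0, 67),
                               dff_percent = rep(2, 100)))
  expect_true(all(unif$dff_percent == 2, na.rm = TRUE))
})

test_that("Gaussian smoothing preserves constants and stays out of slopes", {
  x <- rep(4, 50)
  expect_equal(smooth_gaussian(x), x)
  # smoothing is a separate visualisation step: slope estimators consume
  # the unsmoothed trace and recover the injected slope exactly
  tr <- trace_from_fun(function(t) 0.5 * (t - 2) + 0.3 * sin(40 * t), t_max = 20)
  raw_slope <- ramp_slope_time(tr, 2)
  sm <- dff_trace(tr$time_s, smooth_gaussian(tr$dff_percent, 10))
  expect_false(isTRUE(all.equal(ramp_slope_time(sm, 2), raw_slope)))
})
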