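test_that("previous-ITI regression recovers noiseless and noisy dependencies", {
  tab <- model_trial_table(100, beta = -0.05, noise_sd = 0, seed = 2)
  tab$ramp_slope <- 0.1 - 0.05 * tab$previous_iti_s
  rep <- suppressWarnings(previous_iti_beta(tab))  # exact fit
  expect_equal(rep$beta, -0.05, tolerance = 1e-12)
  expect_equal(rep$intercept, 0.1, tolerance = 1e-12)

  # independence: beta indistinguishable from zero
  null <- model_trial_table(200, beta = 0, seed = 3)
  rn <- previous_iti_beta(null)
  expect_lt(abs(rn$beta), 3 * rn$se)

  # recovery at the scale reported for a single animal
  tab2 <- model_trial_table(300, beta = -0.045, seed = 4)
  r2 <- previous_iti_beta(tab2)
  expect_lt(abs(r2$beta - (-0.045)), 3 * r2$se)

  expect_error(previous_iti_beta(model_trial_table(2, 0)), "at least 3")
  degen <- model_trial_table(10, 0)
  degen$previous_iti_s <- 8
  expect_error(previous_iti_beta(degen), "degenerate")
})

test_that("pooled z-scored regression removes per-animal means", {
  iti <- sample_itis(short_iti_spec(), 100, seed = 5)
  mk <- function(id, m, k) {
    structure(data.frame(trial_index = 1:100,
                         ramp_slope = m + k * iti,
                         previous_iti_s = iti, animal_id = id),
              class = c("trial_table", "data.frame"))
  }
  # same standardized relation, very different raw means/scales
  tabs <- list(a = mk("a", 10, 0.02), b = mk("b", -5, 0.31))
  rep <- pooled_zscore_beta(tabs)
  expect_equal(rep$beta, 1 / sd(iti), tolerance = 1e-10)
  expect_equal(rep$n, 200)

  # z-scores are mean 0, sd 1 per animal by construction
  z <- (tabs$a$ramp_slope - mean(tabs$a$ramp_slope)) / sd(tabs$a$ramp_slope)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  # mixed dependencies pool between the per-animal standardized extremes
  t1 <- model_trial_table(200, -0.06, seed = 6, animal_id = "m1")
  t2 <- model_trial_table(200, -0.02, seed = 7, animal_id = "m2")
  pooled <- pooled_zscore_beta(list(m1 = t1, m2 = t2))
  z1 <- previous_iti_beta(within(t1, ramp_slope <- scale(ramp_slope)[, 1]))$beta
  z2 <- previous_iti_beta(within(t2, ramp_slope <- scale(ramp_slope)[, 1]))$beta
  expect_gte(pooled$beta, min(z1, z2) - 1e-9)
  expect_lte(pooled$beta, max(z1, z2) + 1e-9)

  # zero-variance animal is excluded with a warning
  t3 <- model_trial_table(50, 0, seed = 8, animal_id = "m3")
  t3$ramp_slope <- 0.2
  expect_warning(out <- pooled_zscore_beta(list(m1 = t1, m2 = t2, m3 = t3)),
                 "excluded")
  expect_equal(out$n, 400)
})

test_that("delta-ITI analysis matches its defining arithmetic", {
  tab <- model_trial_table(200, beta = 0, noise_sd = 0, seed = 9)
  tab$ramp_slope <- 0.1 - 0.04 * tab$previous_iti_s
  out <- suppressWarnings(delta_iti_analysis(tab))  # exact fit
  expect_equal(out$beta_delta, -0.04, tolerance = 1e-10)
  # a negative dependency means slope rises after relative ITI decreases
  expect_gt(out$mean_delta_slope_decrease, out$mean_delta_slope_increase)

  # i.i.d. slopes and ITIs: no delta relationship
  null <- model_trial_table(300, beta = 0, seed = 10)
  on <- delta_iti_analysis(null)
  expect_lt(abs(on$beta_delta), 3 * on$se)

  # empty category is reported as missing
  tight <- model_trial_table(20, beta = 0, noise_sd = 0.01, seed = 11)
  tight$previous_iti_s <- 8 + runif(20, 0, 0.5)
  ot <- delta_iti_analysis(tight)
  expect_true(is.na(ot$mean_delta_slope_decrease))
  expect_true(is.na(ot$mean_delta_slope_increase))
})

test_that("averaged previous-ITI regression generalises the single-lag fit", {
  tab <- model_trial_table(300, beta = -0.045, seed = 12)
  r1 <- previous_iti_beta(tab)
  ra <- average_prev_iti_beta(tab, k_back = 1)
  expect_equal(ra$beta, r1$beta, tolerance = 1e-12)

  # single-lag world: averaging over more lags dilutes the evidence
  # (larger standard error), even though the coefficient stays unbiased
  r3 <- average_prev_iti_beta(tab, k_back = 3)
  expect_gt(r3$se, r1$se)

  null <- model_trial_table(300, beta = 0, seed = 13)
  rn <- average_prev_iti_beta(null, k_back = 3)
  expect_lt(abs(rn$beta), 3 * rn$se)

  expect_error(average_prev_iti_beta(model_trial_table(10, 0), 10), "exceeds")
})

test_that("IRI outlier filter is single-pass on the original distribution", {
  expect_equal(filter_iri_outliers(rep(7, 10)), rep(7, 10))

  x <- c(rep(10, 100), 1000)
  kept <- filter_iri_outliers(x)
  expect_equal(kept, rep(10, 100))  # mean 19.8, pop SD 98: only 1000 is out

  y <- c(9, 10, 11, 10, 9.5)
  expect_equal(filter_iri_outliers(y), y)

  # idempotent under the single-pass convention
  set.seed(42)
  z <- rnorm(500)
  expect_identical(filter_iri_outliers(filter_iri_outliers(z)),
                   filter_iri_outliers(z))
})

test_that("condition comparisons run paired tests on per-animal values", {
  same <- condition_comparison(1:9, 1:9)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_difference, 0)

  set.seed(15)
  a <- rnorm(9, 0.3, 0.05)
  b <- rnorm(9, 0.05, 0.05)
  big <- condition_comparison(a, b)
  expect_lt(big$p_value, 0.05)

  flip <- condition_comparison(b, a)
  expect_equal(flip$p_value, big$p_value)
  expect_equal(flip$statistic, -big$statistic)
  expect_error(condition_comparison(1, 2), "at least 2")
})
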