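test_that("sessions are reproducible and their ITIs honour the sampler spec", {
  gt <- ground_truth("SD", n_trials = 15, seed = 77)
  s1 <- generate_photometry_session(gt)
  s2 <- generate_photometry_session(gt)
  expect_identical(s1$ch470, s2$ch470)
  expect_identical(s1$lick_times, s2$lick_times)

  itis <- inter_trial_intervals(s1$events)
  expect_true(all(itis >= 6 & itis <= 12))

  gtL <- ground_truth("LD", seed = 3)
  sL <- generate_photometry_session(gtL, licks = FALSE)
  expect_true(all(inter_trial_intervals(sL$events) >= 6 &
                    inter_trial_intervals(sL$events) <= 186))
  expect_equal(nrow(sL$truths), 40)  # long-ITI sessions are capped at 40 trials
})

test_that("a silent ground truth produces identically zero dF/F", {
  gt <- ground_truth("SF", n_trials = 5, seed = 1,
                     onset_amplitude = 0, reward_amplitude = 0,
                     dip_amplitude = 0, slope_noise_sd = 0,
                     noise_sd = c(ch470 = 0, ch405 = 0),
                     bleach = list(
                       ch405 = list(amps = c(0.2, 0.08), taus = c(300, 1800)),
                       ch470_extra = list(amps = c(0, 0), taus = c(240, 1500))))
  s <- generate_photometry_session(gt, licks = FALSE)
  expect_equal(s$clean_dff, rep(0, length(s$time_s)))
  dff <- session_dff(s)
  expect_lt(max(abs(dff$dff_percent)), 1e-9)
})

test_that("noise-free ramps are recovered exactly from the injected signal
           and near-exactly through the isosbestic pipeline", {
  gt <- ramp_only_gt(n_trials = 20, slope = 0.5)
  s <- generate_photometry_session(gt, licks = FALSE)
  cues <- s$events$time_s[s$events$label == "cue_onset"]

  # exact by construction on the injected percent signal
  tr <- dff_trace(s$time_s, s$clean_dff)
  slopes_clean <- vapply(cues, function(cc) ramp_slope_time(tr, cc), numeric(1))
  expect_equal(slopes_clean, rep(0.5, 20), tolerance = 1e-9)

  # through the full pipeline: limited only by the rank-2 projection
  # leakage of the session-wide isosbestic fit (< 1% of the slope)
  tab <- analyze_pavlovian_session(s)
  expect_lt(max(abs(tab$ramp_slope - 0.5)), 0.01)
  expect_lt(max(abs(tab$pre_cue_slope)), 0.01)
})

test_that("injected onset transients are recovered without noise", {
  gt <- ground_truth("LD", n_trials = 10, seed = 6,
                     onset_amplitude = 2.5, reward_amplitude = 0,
                     dip_amplitude = 0, ramp_slope_base = 0,
                     slope_noise_sd = 0, noise_sd = c(ch470 = 0, ch405 = 0))
  s <- generate_photometry_session(gt, licks = FALSE)
  tab <- analyze_pavlovian_session(s)
  expect_lt(abs(mean(tab$onset_peak) - 2.5), 0.05)
})

test_that("post-reward dip produces a positive pre-cue slope at short ITI", {
  gt <- ground_truth("SD", n_trials = 30, seed = 8,
                     onset_amplitude = 0, reward_amplitude = 0,
                     ramp_slope_base = 0, beta_iti = 0, slope_noise_sd = 0,
                     noise_sd = c(ch470 = 0, ch405 = 0))
  s <- generate_photometry_session(gt, licks = FALSE)
  tab <- analyze_pavlovian_session(s)
  expect_gt(mean(tab$pre_cue_slope[-1]), 0)
})

test_that("a shared multiplicative artifact barely moves recovered slopes", {
  gt <- ramp_only_gt(n_trials = 20, slope = 0.5)
  s <- generate_photometry_session(gt, licks = FALSE)
  base <- analyze_pavlovian_session(s)
  m <- 1 + 0.05 * sin(2 * pi * s$time_s / 120)
  s$ch405 <- s$ch405 * m
  s$ch470 <- s$ch470 * m
  pert <- analyze_pavlovian_session(s)
  expect_lt(max(abs(pert$ramp_slope - base$ramp_slope)), 0.05 * 0.5)
})

test_that("lick generator obeys its rate structure", {
  gt0 <- ground_truth("SD", n_trials = 3, seed = 2,
                      lick_baseline_hz = 0, lick_peak_hz = 0)
  s0 <- generate_photometry_session(gt0)
  expect_length(s0$lick_times, 0)

  # doubling all rates doubles expected counts (Poisson scaling)
  gt1 <- ground_truth("SD", n_trials = 40, seed = 3)
  gt2 <- ground_truth("SD", n_trials = 40, seed = 3,
                      lick_baseline_hz = 4, lick_peak_hz = 12)
  n1 <- length(generate_photometry_session(gt1)$lick_times)
  n2 <- length(generate_photometry_session(gt2)$lick_times)
  expect_lt(abs(n2 / n1 - 2), 0.3)
})

test_that("VR sessions respect the hallway geometry and recover slopes", {
  # near-instant rise to a 20 cm/s plateau: trial lasts about 67/20 s
  gt <- ground_truth("VR-short", n_trials = 5, seed = 4,
                     velocity_rise_tau_s = 0.01,
                     noise_sd = c(ch470 = 0, ch405 = 0), slope_noise_sd = 0)
  s <- generate_vr_session(gt)
  expect_lt(abs(s$truths$trial_duration_s[1] - 67 / 20), 0.02)
  expect_true(all(s$distance$distance_cm <= 67))

  # noise-free distance ramp of 0.1 %/cm recovered through alignment
  gt2 <- ground_truth("VR-short", n_trials = 10, seed = 5,
                      ramp_slope_base = 0.1, slope_noise_sd = 0,
                      onset_amplitude = 0, reward_amplitude = 0,
                      dip_amplitude = 0,
                      noise_sd = c(ch470 = 0, ch405 = 0),
                      bleach = list(
                        ch405 = list(amps = c(0.2, 0.08), taus = c(300, 1800)),
                        ch470_extra = list(amps = c(0, 0), taus = c(240, 1500))))
  s2 <- generate_vr_session(gt2)
  tab <- analyze_vr_session(s2)
  expect_lt(max(abs(tab$ramp_slope - 0.1), na.rm = TRUE), 0.005)

  # velocity metrics from the 50 ms belt stream
  v <- velocity_trace(s2$belt_distance)
  expect_gt(onset_velocity_change(v, s2$events$time_s[1]), 10)
  expect_lt(abs(pre_reward_velocity(v, s2$events$time_s[2]) - 20), 1)
})

test_that("manifests round-trip and detect tampering", {
  gt <- ground_truth("SD", n_trials = 8, seed = 10)
  s <- generate_photometry_session(gt)
  man <- ground_truth_manifest(s)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back$ground_truth$seed, 10)
  expect_equal(back$ground_truth$beta_iti, gt$beta_iti)
  expect_equal(back$truths$ramp_slope, s$truths$ramp_slope, tolerance = 1e-9)

  # the stored seed regenerates the session bit-identically
  gt2 <- do.call(ground_truth, c(list(condition = back$ground_truth$condition,
                                      n_trials = back$ground_truth$n_trials,
                                      seed = back$ground_truth$seed)))
  expect_identical(generate_photometry_session(gt2)$ch470, s$ch470)

  txt <- readLines(path)
  writeLines(gsub("-0.045", "-0.099", txt, fixed = TRUE), path)
  expect_error(read_manifest(path), "checksum")

  plain <- photometry_session(s$time_s, s$ch470, s$ch405, s$events)
  expect_error(ground_truth_manifest(plain), "not a synthetic session")
})

test_that("sessions round-trip through CSV files", {
  gt <- ground_truth("SD", n_trials = 3, seed = 11)
  s <- generate_photometry_session(gt, licks = FALSE)
  sig <- withr::local_tempfile(fileext = ".csv")
  ev <- withr::local_tempfile(fileext = ".csv")
  write_photometry_session(s, sig, ev)
  back <- read_photometry_session(sig, ev)
  expect_equal(back$ch470, s$ch470, tolerance = 1e-10)
  expect_equal(back$events$label, s$events$label)
})
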