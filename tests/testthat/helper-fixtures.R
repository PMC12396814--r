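# Shared fixtures, built in code at test time.

short_iti_spec <- function() calibrate_truncated_exponential(6, 12, 8)
long_iti_spec <- function() calibrate_truncated_exponential(6, 186, 55)

# A noise-free ground truth containing only the within-cue ramp, used for
# exact-construction recovery checks.
ramp_only_gt <- function(n_trials = 20, seed = 5, slope = 0.5, beta = 0) {
  ground_truth("SD", n_trials = n_trials, seed = seed,
               onset_amplitude = 0, reward_amplitude = 0, dip_amplitude = 0,
               ramp_slope_base = slope, beta_iti = beta, slope_noise_sd = 0,
               noise_sd = c(ch470 = 0, ch405 = 0),
               bleach = list(
                 ch405 = list(amps = c(0.20, 0.08), taus = c(300, 1800)),
                 ch470_extra = list(amps = c(0, 0), taus = c(240, 1500))))
}

# A regular 120 Hz dF/F trace from a function of time.
trace_from_fun <- function(f, t_max = 30, fs = 120) {
  tt <- seq(0, t_max, by = 1 / fs)
  dff_trace(tt, f(tt))
}

# Trial table drawn directly from the statistical model of the ramp-slope/
# ITI dependency (no photometry), for fast statistics tests.
model_trial_table <- function(n, beta, base = 0.6, noise_sd = 0.15,
                              seed = 1, animal_id = "a1") {
  set.seed(seed)
  iti <- sample_itis(short_iti_spec(), n)
  slope <- base + beta * iti + rnorm(n, 0, noise_sd)
  structure(
    data.frame(trial_index = seq_len(n), ramp_slope = slope,
               previous_iti_s = iti, animal_id = animal_id),
    class = c("trial_table", "data.frame")
  )
}
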