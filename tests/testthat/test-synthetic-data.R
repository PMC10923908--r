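test_that("config invariants are enforced", {
  expect_error(sim_config(duration = 0), "duration")
  expect_error(sim_config(so_freq_low = 2, so_freq_high = 1), "so_freq_low")
  expect_error(sim_config(so_trough_amp_mean = -60), "-75")
  expect_error(sim_config(duration = 60, so_rate = 4,
                          stage_plan = data.frame(stage = "N2",
                                                  duration = 60)),
               "no N3")
  expect_error(sim_config(duration = 60,
                          stage_plan = data.frame(stage = "N3",
                                                  duration = 50)),
               "sum to duration")
})

test_that("so_rate = 0 gives a noise-only recording with empty ground truth", {
  g <- generate_sleep_eeg(sim_config(duration = 20, n_channels = 4,
                                     so_rate = 0, noise_scale = 5,
                                     seed = 1))
  expect_length(g$ground_truth$so_trough_times, 0)
  expect_lt(max(abs(g$recording$data)), 50) # noise scale, no 100 uV events
  expect_true(all(is.finite(g$recording$data)))
  expect_true("F3" %in% g$recording$channel_labels)
})

test_that("SO count over 10 min of N3 matches the configured rate", {
  g <- generate_sleep_eeg(sim_config(duration = 600, n_channels = 2,
                                     so_rate = 8, noise_scale = 5,
                                     seed = 11))
  n <- length(g$ground_truth$so_trough_times)
  expect_lt(abs(n - 80), 3 * sqrt(80)) # Poisson-scale sampling error
})

test_that("-100 uV events cross -80 uV in the slow-wave-filtered F3 trace", {
  g <- generate_sleep_eeg(sim_config(duration = 120, n_channels = 4,
                                     so_rate = 10, noise_scale = 3,
                                     so_trough_amp_mean = -100,
                                     so_trough_amp_sd = 1, seed = 3))
  fs <- g$recording$sampling_rate
  bf <- signal::butter(2, c(0.5, 4) / (fs / 2), type = "pass")
  f3 <- signal::filtfilt(bf, g$recording$data["F3", ])
  at_troughs <- f3[round(g$ground_truth$so_trough_times * fs) + 1]
  expect_true(all(at_troughs < -80))
})

test_that("identical seeds reproduce recordings bit-identically", {
  cfg <- sim_config(duration = 30, n_channels = 4, so_rate = 6,
                    arousal_rate = 10, seed = 99)
  g1 <- generate_sleep_eeg(cfg)
  g2 <- generate_sleep_eeg(cfg)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$ground_truth, g2$ground_truth)
  expect_identical(g1$recording$arousals, g2$recording$arousals)
})

test_that("SO placement respects the hypnogram (N3 only)", {
  plan <- data.frame(stage = c("N2", "N3", "REM", "N3"),
                     duration = c(60, 120, 60, 120))
  g <- generate_sleep_eeg(sim_config(duration = 360, n_channels = 2,
                                     so_rate = 10, stage_plan = plan,
                                     seed = 5))
  tt <- g$ground_truth$so_trough_times
  expect_gt(length(tt), 10)
  in_n3 <- (tt >= 60 & tt < 180) | (tt >= 240 & tt < 360)
  expect_true(all(in_n3))
  # hypnogram reflects the plan, one stage per 30-s epoch
  expect_length(g$recording$hypnogram, 12)
  expect_identical(g$recording$hypnogram[1:2], c("N2", "N2"))
  expect_identical(g$recording$hypnogram[3], "N3")
})

test_that("spindles overlap the up-phase of their SO", {
  g <- generate_sleep_eeg(sim_config(duration = 300, n_channels = 2,
                                     so_rate = 8, spindle_prob_per_so = 1,
                                     seed = 21))
  sp <- g$ground_truth$spindle_intervals
  expect_gt(nrow(sp), 10)
  centre <- rowMeans(sp)
  near_peak <- vapply(centre, function(cc)
    min(abs(g$ground_truth$so_peak_times - cc)) < 0.05, logical(1))
  expect_true(all(near_peak))
})

test_that("zero-amplitude injected effect leaves the recording untouched", {
  g <- generate_sleep_eeg(sim_config(duration = 20, n_channels = 4,
                                     so_rate = 0, seed = 2))
  ev <- data.frame(onset = c(5, 10), condition = "Up",
                   sound_type = c("Experimental", "Novel"))
  out <- inject_condition_effects(g$recording, ev, list(
    list(sound_type = "Experimental", window = c(0.2, 0.4),
         amplitude = 0)))
  expect_identical(out$data, g$recording$data)
})

test_that("frontal-topography effect is maximal at frontal channels", {
  g <- generate_sleep_eeg(sim_config(duration = 40, n_channels = 16,
                                     so_rate = 0, noise_scale = 0.01,
                                     seed = 2))
  ev <- data.frame(onset = seq(2, 38, by = 4), condition = "Up",
                   sound_type = "Experimental")
  out <- inject_condition_effects(g$recording, ev, list(
    list(sound_type = "Experimental", window = c(0.1, 0.3),
         amplitude = 10)))
  diff_amp <- apply(out$data - g$recording$data, 1, function(ch) max(abs(ch)))
  top <- g$recording$channel_labels[which.max(diff_amp)]
  expect_true(top %in% c("F3", "Fz", "F4"))
})

test_that("an event outside the recording is rejected by index", {
  g <- generate_sleep_eeg(sim_config(duration = 10, n_channels = 2,
                                     so_rate = 0, seed = 2))
  ev <- data.frame(onset = c(2, 9.9), condition = "Up",
                   sound_type = "Experimental")
  expect_error(inject_condition_effects(g$recording, ev, list(
    list(sound_type = "Experimental", window = c(0, 0.5),
         amplitude = 5))), "event 2")
})

test_that("behaviour generator is calibrated at chance", {
  ta <- data.frame(condition = "Up", session = 2, pair_class = "deg2",
                   p = 0.5)
  cfg <- behaviour_sim_config(50, ta, subject_effect_sd = 0,
                              trials_per_cell = 100, seed = 4)
  b <- generate_behaviour(cfg)
  se <- sqrt(0.25 / nrow(b))
  expect_lt(abs(mean(b$correct) - 0.5), 3 * se)
})

test_that("behaviour generator recovers a configured condition difference", {
  ta <- data.frame(condition = c("Up", "Control"), session = 2,
                   pair_class = "deg2", p = c(0.8, 0.55))
  cfg <- behaviour_sim_config(20, ta, subject_effect_sd = 0.2,
                              trials_per_cell = 40, seed = 8)
  b <- generate_behaviour(cfg)
  m <- tapply(b$correct, b$condition, mean)
  d <- m[["Up"]] - m[["Control"]]
  se <- sqrt(0.25 / (20 * 40)) * sqrt(2)
  expect_lt(abs(d - 0.25), max(2 * se, 0.04))
})

test_that("degenerate behaviour configs are rejected", {
  ta <- data.frame(condition = "Up", session = 1, pair_class = "premise",
                   p = 0.7)
  expect_error(behaviour_sim_config(10, ta, trials_per_cell = 0),
               "trials_per_cell")
  expect_error(behaviour_sim_config(10, ta[0, ]), "non-empty")
  expect_error(behaviour_sim_config(10, transform(ta, p = 1.2)),
               "probabilities")
  cfg <- behaviour_sim_config(5, ta, seed = 1)
  expect_identical(generate_behaviour(cfg), generate_behaviour(cfg))
})
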