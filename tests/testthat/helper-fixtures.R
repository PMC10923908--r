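# shared fixture builders; everything is generated in code at test time

# three hierarchies, one per condition/category
make_hierarchies <- function() {
  list(hierarchy("Up", "faces"),
       hierarchy("Down", "scenes"),
       hierarchy("Control", "objects"))
}

# contiguous 1 Hz SO train (troughs every second), all N3
so_train_config <- function(duration = 150, n_channels = 8, seed = 42,
                            noise_scale = 2) {
  sim_config(sampling_rate = 500, n_channels = n_channels,
             duration = duration, so_rate = 60,
             so_freq_low = 0.999, so_freq_high = 1.001, so_spacing = 1,
             so_trough_amp_mean = -100, so_trough_amp_sd = 0.1,
             spindle_prob_per_so = 0, noise_scale = noise_scale,
             seed = seed)
}

# single-condition schedule for phase-targeting runs
flat_schedule <- function(condition, n = 40) {
  data.frame(block = 1L, condition = rep(condition, n),
             sound_type = "Experimental", item = "A",
             stringsAsFactors = FALSE)
}

# pure-tone multichannel recording with all-N3 hypnogram
tone_recording <- function(freq = 1, amp = 100, duration = 120, fs = 500,
                           labels = c("F3", "Fz", "Cz")) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- amp * cos(2 * pi * freq * t - pi) # trough at t = 0, 1/freq, ...
  sleep_recording(matrix(rep(x, length(labels)), nrow = length(labels),
                         byrow = TRUE),
                  sampling_rate = fs, channel_labels = labels)
}

# one simulated decoding subject: noise EEG + planted Experimental-only
# evoked response in `window`, decoded with LDA/AUC on a decimated grid
simulate_decoding_subject <- function(seed, effect_amp = 20,
                                      window = c(1.2, 1.3),
                                      n_events = 60, n_channels = 16,
                                      time_decim = 5) {
  gap <- 4.6
  dur <- n_events * gap + 8
  cfg <- sim_config(sampling_rate = 100, n_channels = n_channels,
                    duration = dur, so_rate = 0,
                    so_trough_amp_mean = -100, noise_scale = 10,
                    seed = seed)
  g <- generate_sleep_eeg(cfg)
  ev <- data.frame(onset = 4 + (seq_len(n_events) - 1) * gap,
                   condition = "Up",
                   sound_type = rep(c("Experimental", "Novel"),
                                    length.out = n_events),
                   stringsAsFactors = FALSE)
  rec <- if (effect_amp != 0)
    inject_condition_effects(g$recording, ev, list(
      list(sound_type = "Experimental", window = window,
           amplitude = effect_amp)))
  else g$recording
  ep <- epoch_recording(rec, ev, window = c(-1, 3))
  dc <- decoding_config(classifiers = "lda", metrics = "auc", folds = 5,
                        repetitions = 2, pca_components = 10,
                        time_decim = time_decim, seed = seed + 1)
  decode_timecourse(ep, dc)
}
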