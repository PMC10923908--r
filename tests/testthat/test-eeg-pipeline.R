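test_that("preprocessing removes DC, attenuates 50 Hz, and re-references", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  labs <- c("F3", "Cz", "M1", "M2")
  base <- rbind(50 + sin(2 * pi * 2 * t), 50 + sin(2 * pi * 50 * t),
                0 * t, 0 * t)
  rec <- sleep_recording(base, fs, channel_labels = labs)
  out <- preprocess(rec)
  mid <- seq(5 * fs, 15 * fs)
  expect_lt(abs(mean(out$data["F3", mid])), 1)      # DC gone
  amp50 <- max(abs(out$data["Cz", mid]))
  expect_lt(amp50, 0.1)                             # >= 20 dB down
  # re-referencing to linked mastoids is idempotent
  out2 <- preprocess(out, l_freq = NULL, h_freq = NULL)
  expect_equal(out2$data, out$data, tolerance = 1e-10)
})

test_that("preprocessing warns without mastoids and interpolates bad channels", {
  g <- generate_sleep_eeg(sim_config(duration = 10, n_channels = 8,
                                     so_rate = 0, seed = 3))
  expect_warning(preprocess(g$recording), "mastoid")
  bad <- g$recording
  bad$data["F3", ] <- 1e4
  out <- suppressWarnings(preprocess(bad, l_freq = NULL, h_freq = NULL,
                                     bad_channels = "F3"))
  expect_lt(max(abs(out$data["F3", ])), 100)
  expect_error(preprocess(g$recording,
                          bad_channels = g$recording$channel_labels),
               "all channels")
})

test_that("epoching yields 4-s segments with metadata in input order", {
  g <- generate_sleep_eeg(sim_config(duration = 30, n_channels = 4,
                                     so_rate = 0, seed = 5))
  ev <- data.frame(onset = c(10, 5, 15), condition = c("Up", "Down", "Up"),
                   sound_type = "Experimental")
  ep <- epoch_recording(g$recording, ev, window = c(-1, 3))
  expect_equal(dim(ep$data), c(3, 4, 2000)) # 4 s at 500 Hz
  expect_equal(ep$metadata$onset, c(10, 5, 15))
  expect_equal(range(ep$times), c(-1, 3 - 1 / 500))
  # boundary events are dropped with a message
  ev2 <- rbind(ev, data.frame(onset = 29.5, condition = "Up",
                              sound_type = "Novel"))
  expect_message(ep2 <- epoch_recording(g$recording, ev2), "dropped")
  expect_equal(dim(ep2$data)[1], 3)
  expect_error(epoch_recording(g$recording, ev[0, ]), "no events")
})

test_that("ERPs average correctly and planted effects are localised", {
  g <- generate_sleep_eeg(sim_config(duration = 60, n_channels = 4,
                                     so_rate = 0, noise_scale = 1,
                                     seed = 7))
  ev <- data.frame(onset = seq(5, 50, by = 5),
                   condition = "Up",
                   sound_type = rep(c("Experimental", "Novel"), 5))
  rec <- inject_condition_effects(g$recording, ev, list(
    list(sound_type = "Experimental", window = c(0.5, 0.7),
         amplitude = 30)))
  ep <- epoch_recording(rec, ev, window = c(-0.5, 1.5))
  erp <- compute_erp(ep)
  dmean <- erp$cells[["Up/Experimental"]]$mean -
    erp$cells[["Up/Novel"]]$mean
  f3 <- match("F3", ep$channel_labels)
  inside <- ep$times >= 0.5 & ep$times <= 0.7
  expect_gt(max(abs(dmean[f3, inside])), 20)
  expect_lt(max(abs(dmean[f3, !inside])), 10)
})

test_that("ERP algebra: identical epochs, cancellation, linearity", {
  fs <- 100
  dat <- array(0, dim = c(4, 2, 50))
  for (e in 1:4) dat[e, , ] <- matrix(sin(seq_len(50) / 5), 2, 50,
                                      byrow = TRUE)
  ep <- structure(list(data = dat, times = seq_len(50) / fs - 0.25,
                       sampling_rate = fs, channel_labels = c("F3", "Cz"),
                       metadata = data.frame(condition = "Up",
                                             sound_type = "Experimental")[rep(1, 4), ]),
                  class = "epoch_set")
  erp <- compute_erp(ep)
  cell <- erp$cells[[1]]
  expect_equal(cell$mean[1, ], sin(seq_len(50) / 5))
  expect_equal(max(cell$sem), 0)
  # +x and -x in equal numbers cancel
  dat2 <- dat
  dat2[3:4, , ] <- -dat2[3:4, , ]
  ep$data <- dat2
  expect_lt(max(abs(compute_erp(ep)$cells[[1]]$mean)), 1e-12)
  # pooled ERP is the weighted mean of sub-group ERPs
  ep$metadata$sound_type <- c("Experimental", "Experimental",
                              "Experimental", "Novel")
  erp3 <- compute_erp(ep)
  pooled <- compute_erp(ep, by = NULL)$cells[["all"]]$mean
  w <- (3 * erp3$cells[["Up/Experimental"]]$mean +
          1 * erp3$cells[["Up/Novel"]]$mean) / 4
  expect_equal(pooled, w, tolerance = 1e-12)
})

test_that("Morlet TFR peaks at the tone frequency", {
  fs <- 200
  t <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  dat <- array(0, dim = c(2, 1, length(t)))
  dat[1, 1, ] <- sin(2 * pi * 10 * t)
  dat[2, 1, ] <- sin(2 * pi * 10 * t)
  ep <- structure(list(data = dat, times = t, sampling_rate = fs,
                       channel_labels = "F3",
                       metadata = data.frame(condition = c("Up", "Up"))),
                  class = "epoch_set")
  tfr <- morlet_tfr(ep, freqs = seq(4, 20, by = 1),
                    times = seq(-0.5, 2, by = 0.1))
  pk <- apply(tfr$power[1, 1, , ], 2, which.max)
  expect_true(all(tfr$freqs[pk] == 10))
  expect_error(morlet_tfr(ep, freqs = c(10, 150)), "Nyquist")
})

test_that("a planted theta burst is recovered at the right time and band", {
  fs <- 200
  t <- seq(-1, 3 - 1 / fs, by = 1 / fs)
  set.seed(8)
  dat <- array(rnorm(6 * 1 * length(t), sd = 0.5), dim = c(6, 1, length(t)))
  burst <- t >= 1 & t <= 1.5
  for (e in 1:6)
    dat[e, 1, burst] <- dat[e, 1, burst] +
      3 * sin(2 * pi * 6 * t[burst]) * sin(pi * seq_len(sum(burst)) / sum(burst))
  ep <- structure(list(data = dat, times = t, sampling_rate = fs,
                       channel_labels = "F3",
                       metadata = data.frame(condition = rep("Up", 6))),
                  class = "epoch_set")
  tfr <- morlet_tfr(ep, freqs = seq(4, 20, by = 1),
                    times = seq(-0.5, 2.4, by = 0.1), average = TRUE)
  tfr <- baseline_normalize(tfr)
  p <- tfr$power[1, , ] # freqs x times
  hot <- which(p == max(p), arr.ind = TRUE)
  expect_true(tfr$freqs[hot[1]] %in% 5:8)  # theta band
  expect_true(abs(tfr$times[hot[2]] - 1.25) <= 0.5) # within half-width
})

test_that("relative-change baseline normalisation has closed-form values", {
  tfr <- structure(list(power = array(2, dim = c(1, 1, 10)),
                        freqs = 10, times = seq(-0.9, 0.9, by = 0.2),
                        channel_labels = "F3", baseline_mode = "raw"),
                   class = "tfr")
  # stationary -> 0 everywhere
  out <- baseline_normalize(tfr, baseline = c(-0.9, -0.1))
  expect_equal(max(abs(out$power)), 0)
  # doubled and halved post-cue power
  tfr$power[1, 1, 6:10] <- 4
  out2 <- baseline_normalize(tfr, baseline = c(-0.9, -0.1))
  expect_equal(unique(out2$power[1, 1, 6:10]), 1)
  tfr$power[1, 1, 6:10] <- 1
  out3 <- baseline_normalize(tfr, baseline = c(-0.9, -0.1))
  expect_equal(unique(out3$power[1, 1, 6:10]), -0.5)
  tfr$power[] <- 0
  expect_error(baseline_normalize(tfr, baseline = c(-0.9, -0.1)), "zero")
})
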