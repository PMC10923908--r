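#' Simulation configuration for synthetic sleep EEG
#'
#' Parameters of the slow-wave-sleep EEG generator. The defaults describe a
#' generic N3 recording: frontally dominant slow oscillations (SOs) in the
#' 0.5-1.5 Hz band with trough amplitudes around -100 uV, spindles (9-16 Hz)
#' coupled to the SO positive peak, and 1/f background noise.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param n_channels number of scalp channels (labels from
#'   [standard_montage()], always including F3).
#' @param duration recording length in seconds.
#' @param so_rate SO events per minute within N3 sleep.
#' @param so_freq_low,so_freq_high SO frequency band in Hz; each event's
#'   frequency is drawn uniformly from this band.
#' @param so_trough_amp_mean,so_trough_amp_sd trough amplitude (uV, negative)
#'   mean and SD at the source maximum. The mean must lie below -75 uV so the
#'   -80 uV online detection threshold is reachable.
#' @param so_peak_ratio positive-peak amplitude as a fraction of the trough
#'   amplitude (1 = symmetric biphasic wave).
#' @param so_asym ratio of peak half-wave duration to trough half-wave
#'   duration (1 = symmetric).
#' @param so_spacing if non-NULL, SOs are placed on a regular grid with this
#'   onset-to-onset spacing (s) instead of a random renewal process; used for
#'   densely packed trains with known timing.
#' @param spindle_freq_low,spindle_freq_high spindle band in Hz.
#' @param spindle_prob_per_so probability that an SO carries a spindle burst
#'   centred on its positive peak.
#' @param noise_exponent 1/f^a background slope a.
#' @param noise_scale background noise SD in uV per channel.
#' @param stage_plan data.frame with columns `stage` and `duration` (s)
#'   describing the hypnogram; durations must sum to `duration`. Default:
#'   all N3.
#' @param arousal_rate arousal events per hour (metadata intervals only).
#' @param include_mastoids append M1/M2 channels (no SO mixing) so the
#'   offline linked-mastoid re-reference can be exercised.
#' @param seed integer RNG seed; identical seeds reproduce the recording
#'   bit-identically.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 500, n_channels = 60, duration = 60,
                       so_rate = 8, so_freq_low = 0.5, so_freq_high = 1.5,
                       so_trough_amp_mean = -100, so_trough_amp_sd = 10,
                       so_peak_ratio = 1, so_asym = 1, so_spacing = NULL,
                       spindle_freq_low = 9, spindle_freq_high = 16,
                       spindle_prob_per_so = 0.3,
                       noise_exponent = 1, noise_scale = 10,
                       stage_plan = NULL, arousal_rate = 0,
                       include_mastoids = FALSE, seed = NULL) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (so_freq_low >= so_freq_high) stop("so_freq_low must be < so_freq_high")
  if (so_rate > 0 && so_trough_amp_mean > -75)
    stop("so_trough_amp_mean must be below -75 uV (detector threshold -80 uV)")
  if (spindle_freq_low >= spindle_freq_high)
    stop("spindle_freq_low must be < spindle_freq_high")
  if (is.null(stage_plan))
    stage_plan <- data.frame(stage = "N3", duration = duration)
  if (!all(c("stage", "duration") %in% names(stage_plan)))
    stop("stage_plan needs columns stage, duration")
  if (abs(sum(stage_plan$duration) - duration) > 1e-9)
    stop("stage_plan durations must sum to duration")
  if (so_rate > 0 && !any(stage_plan$stage == "N3"))
    stop("stage_plan has no N3 segment but so_rate > 0")
  structure(list(
    sampling_rate = sampling_rate, n_channels = n_channels,
    duration = duration, so_rate = so_rate,
    so_freq_low = so_freq_low, so_freq_high = so_freq_high,
    so_trough_amp_mean = so_trough_amp_mean,
    so_trough_amp_sd = so_trough_amp_sd,
    so_peak_ratio = so_peak_ratio, so_asym = so_asym,
    so_spacing = so_spacing,
    spindle_freq_low = spindle_freq_low,
    spindle_freq_high = spindle_freq_high,
    spindle_prob_per_so = spindle_prob_per_so,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    stage_plan = stage_plan, arousal_rate = arousal_rate,
    include_mastoids = include_mastoids, seed = seed),
    class = "sim_config")
}

# 1/f^a noise via spectral shaping of white Gaussian noise, unit variance.
pink_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  sp <- stats::fft(white)
  f <- c(1e-6, seq_len(n - 1)) # pseudo-frequencies; DC kept tiny
  f <- pmin(f, n - f)          # fold to two-sided
  shape <- f ^ (-exponent / 2)
  x <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# raised-cosine biphasic SO template sampled at fs; returns waveform plus
# trough/peak times relative to event onset. Trough amplitude follows the
# sleep-scoring convention: it is the depth of the event in the 0.5-4 Hz
# slow-wave band (zero-phase filtered), not the raw template depth, so a
# -100 uV event stays below a -80 uV band-filtered detection threshold.
so_template <- function(freq, amp_trough, peak_ratio, asym, fs) {
  period <- 1 / freq
  t_tr <- period / (1 + asym)        # trough half-wave duration
  t_pk <- period - t_tr
  n_tr <- max(2L, round(t_tr * fs))
  n_pk <- max(2L, round(t_pk * fs))
  u <- seq_len(n_tr) / n_tr
  v <- seq_len(n_pk) / n_pk
  w <- c(-abs(amp_trough) * (1 - cos(2 * pi * u)) / 2,
         abs(amp_trough) * peak_ratio * (1 - cos(2 * pi * v)) / 2)
  w <- w * sw_band_gain(freq, peak_ratio, asym, fs)
  list(wave = w, trough = (n_tr / 2) / fs, peak = (n_tr + n_pk / 2) / fs,
       duration = (n_tr + n_pk) / fs)
}

# inverse attenuation of an isolated unit template in the 0.5-4 Hz band
# (zero-phase), cached per parameter combination
.sw_gain_cache <- new.env(parent = emptyenv())
sw_band_gain <- function(freq, peak_ratio, asym, fs) {
  key <- paste(round(freq, 3), peak_ratio, asym, fs)
  hit <- .sw_gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  period <- 1 / freq
  n_tr <- max(2L, round(period / (1 + asym) * fs))
  n_pk <- max(2L, round((period - period / (1 + asym)) * fs))
  w <- c(-(1 - cos(2 * pi * seq_len(n_tr) / n_tr)) / 2,
         peak_ratio * (1 - cos(2 * pi * seq_len(n_pk) / n_pk)) / 2)
  pad <- round(2 * period * fs)
  bf <- signal::butter(2, c(0.5, 4) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, c(numeric(pad), w, numeric(pad)))
  g <- 1 / abs(min(y))
  .sw_gain_cache[[key]] <- g
  g
}

# frontal-maximal mixing weights for the SO source, calibrated so the
# configured trough amplitude is realised at the F3 detection channel
frontal_weights <- function(montage) {
  w <- 0.3 + 0.7 * exp(-((montage$x)^2 + (montage$y - 0.6)^2) / 0.35)
  f3 <- match("F3", montage$label)
  if (!is.na(f3)) w <- w / w[f3]
  w
}

# central mixing weights for spindle bursts
central_weights <- function(montage) {
  0.2 + 0.8 * exp(-((montage$x)^2 + (montage$y)^2) / 0.35)
}

#' Generate a synthetic sleep-EEG recording with ground truth
#'
#' Synthesises a multichannel N3 recording containing slow oscillations
#' (one-period raised-cosine biphasic waves: trough half-wave then peak
#' half-wave, so trough and peak times are analytically known), SO-coupled
#' spindle bursts, 1/f background noise, a hypnogram, and arousal intervals.
#' SOs are placed only within N3 segments of the stage plan.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (class `sleep_recording`: `data`
#'   channels x samples matrix in uV, `channel_labels`, `sampling_rate`,
#'   `hypnogram` one stage per 30-s epoch, `arousals` data.frame start/end s,
#'   `montage`) and `ground_truth` (`so_trough_times`, `so_peak_times`,
#'   `spindle_intervals`).
#' @export
generate_sleep_eeg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  montage <- standard_montage(config$n_channels,
                              include_mastoids = config$include_mastoids)
  n_ch <- nrow(montage)

  # per-sample stage vector + hypnogram per 30-s epoch
  seg_end <- cumsum(config$stage_plan$duration)
  seg_start <- c(0, seg_end[-length(seg_end)])
  t_samp <- (seq_len(n) - 1) / fs
  stage_of <- function(tt) {
    i <- findInterval(tt, seg_start)
    config$stage_plan$stage[pmin(i, nrow(config$stage_plan))]
  }
  n_epochs <- ceiling(config$duration / 30)
  hypnogram <- stage_of(pmin((seq_len(n_epochs) - 1) * 30,
                             config$duration - 1e-9))

  # SO placement within N3 segments
  trough_times <- numeric(0); peak_times <- numeric(0)
  so_source <- numeric(n)
  sp_int <- matrix(numeric(0), ncol = 2)
  sp_source <- numeric(n)
  mean_dur <- log(config$so_freq_high / config$so_freq_low) /
    (config$so_freq_high - config$so_freq_low) # E[1/f], f ~ U(low, high)
  n3 <- which(config$stage_plan$stage == "N3")
  if (config$so_rate > 0) for (si in n3) {
    s0 <- seg_start[si]; s1 <- seg_end[si]
    if (!is.null(config$so_spacing)) {
      onsets <- seq(s0, s1 - 1 / config$so_freq_low, by = config$so_spacing)
    } else {
      gap_rate <- 1 / max(1 / (config$so_rate / 60) - mean_dur, 0.05)
      onsets <- c(); tt <- s0 + stats::rexp(1, config$so_rate / 60)
      while (tt < s1 - 2 / config$so_freq_low) {
        onsets <- c(onsets, tt)
        tt <- tt + mean_dur + stats::rexp(1, gap_rate)
      }
    }
    for (on in onsets) {
      f <- stats::runif(1, config$so_freq_low, config$so_freq_high)
      a <- min(stats::rnorm(1, config$so_trough_amp_mean,
                            config$so_trough_amp_sd), -20)
      tpl <- so_template(f, a, config$so_peak_ratio, config$so_asym, fs)
      i0 <- round(on * fs) + 1L
      i1 <- min(i0 + length(tpl$wave) - 1L, n)
      if (i1 <= i0) next
      so_source[i0:i1] <- so_source[i0:i1] + tpl$wave[seq_len(i1 - i0 + 1L)]
      trough_times <- c(trough_times, on + tpl$trough)
      peak_times <- c(peak_times, on + tpl$peak)
      if (stats::runif(1) < config$spindle_prob_per_so) {
        sf <- stats::runif(1, config$spindle_freq_low, config$spindle_freq_high)
        sdur <- stats::runif(1, 0.5, 1)
        sc <- on + tpl$peak
        j0 <- max(1L, round((sc - sdur / 2) * fs) + 1L)
        j1 <- min(n, round((sc + sdur / 2) * fs))
        if (j1 > j0) {
          tj <- (seq(j0, j1) - 1) / fs
          env <- sin(pi * (tj - tj[1]) / (tj[length(tj)] - tj[1]))^2
          sp_source[j0:j1] <- sp_source[j0:j1] +
            20 * env * sin(2 * pi * sf * (tj - sc))
          sp_int <- rbind(sp_int, c(tj[1], tj[length(tj)]))
        }
      }
    }
  }

  w_so <- frontal_weights(montage)
  w_sp <- central_weights(montage)
  if (config$include_mastoids) {
    mast <- montage$label %in% c("M1", "M2")
    w_so[mast] <- 0.1; w_sp[mast] <- 0.05
  }
  data <- outer(w_so, so_source) + outer(w_sp, sp_source)
  for (ch in seq_len(n_ch))
    data[ch, ] <- data[ch, ] + config$noise_scale * pink_noise(n, config$noise_exponent)
  rownames(data) <- montage$label

  # arousals: metadata intervals, no waveform change
  arousals <- data.frame(start = numeric(0), end = numeric(0))
  if (config$arousal_rate > 0) {
    n_ar <- stats::rpois(1, config$arousal_rate * config$duration / 3600)
    if (n_ar > 0) {
      st <- sort(stats::runif(n_ar, 0, config$duration - 15))
      arousals <- data.frame(start = st,
                             end = pmin(st + stats::runif(n_ar, 5, 15),
                                        config$duration))
    }
  }

  rec <- structure(list(data = data, channel_labels = montage$label,
                        sampling_rate = fs, hypnogram = hypnogram,
                        arousals = arousals, montage = montage),
                   class = "sleep_recording")
  gt <- structure(list(so_trough_times = trough_times,
                       so_peak_times = peak_times,
                       spindle_intervals = sp_int),
                  class = "ground_truth")
  list(recording = rec, ground_truth = gt)
}

#' Construct a sleep recording from raw arrays
#'
#' Wraps a channels x samples matrix with the metadata the pipeline
#' expects; used when loading external data or building oracle signals.
#'
#' @param data channels x samples numeric matrix (uV); rownames used as
#'   channel labels when `channel_labels` is missing.
#' @param sampling_rate Hz.
#' @param channel_labels character vector, one per row of `data`.
#' @param hypnogram stage per 30-s epoch; default all "N3".
#' @param arousals data.frame with `start`, `end` (s); default none.
#' @param montage data.frame with label/x/y; defaults to
#'   [standard_montage()] positions matched by label (NA coordinates for
#'   unknown labels).
#' @return object of class `sleep_recording`.
#' @export
sleep_recording <- function(data, sampling_rate, channel_labels = rownames(data),
                            hypnogram = NULL, arousals = NULL,
                            montage = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels) || length(channel_labels) != nrow(data))
    stop("channel_labels must name every row of data")
  if (!all(is.finite(data))) stop("data contains non-finite samples")
  dur <- ncol(data) / sampling_rate
  if (is.null(hypnogram)) hypnogram <- rep("N3", ceiling(dur / 30))
  if (is.null(arousals))
    arousals <- data.frame(start = numeric(0), end = numeric(0))
  if (is.null(montage)) {
    std <- standard_montage(60, include_mastoids = TRUE)
    montage <- data.frame(label = channel_labels,
                          x = std$x[match(channel_labels, std$label)],
                          y = std$y[match(channel_labels, std$label)],
                          stringsAsFactors = FALSE)
  }
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, hypnogram = hypnogram,
                 arousals = arousals, montage = montage),
            class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf("<sleep_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(sprintf("  hypnogram: %d x 30-s epochs (%s); %d arousal interval(s)\n",
              length(x$hypnogram),
              paste(unique(x$hypnogram), collapse = ","),
              nrow(x$arousals)))
  invisible(x)
}

#' Inject condition-specific evoked effects into a recording
#'
#' Additively plants a multivariate evoked difference (and optionally an
#' oscillatory power modulation) time-locked to a subset of cue events, so
#' downstream ERP/TFR/decoding stages have a recoverable ground-truth effect.
#'
#' @param recording a `sleep_recording`.
#' @param events data.frame with at least `onset` (s), and the columns named
#'   by `effect_spec` selectors (`condition`, `sound_type`).
#' @param effect_spec a list of effect descriptions; each element is a list
#'   with fields: `sound_type` and/or `condition` (selector, NULL = any),
#'   `window` = c(start, end) seconds relative to cue onset, `amplitude` uV,
#'   optional `topography` (numeric vector over channels; default frontal
#'   weights), optional `osc_freq` Hz (if set, a Hann-windowed oscillatory
#'   burst is planted instead of a monophasic deflection).
#' @return modified `sleep_recording` (input untouched).
#' @export
inject_condition_effects <- function(recording, events, effect_spec) {
  stopifnot(inherits(recording, "sleep_recording"))
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  data <- recording$data
  for (spec in effect_spec) {
    topo <- spec$topography
    if (is.null(topo)) topo <- frontal_weights(recording$montage)
    if (length(topo) != nrow(data))
      stop("topography length must equal channel count")
    sel <- rep(TRUE, nrow(events))
    if (!is.null(spec$sound_type)) sel <- sel & events$sound_type == spec$sound_type
    if (!is.null(spec$condition)) sel <- sel & events$condition == spec$condition
    for (k in which(sel)) {
      i0 <- round((events$onset[k] + spec$window[1]) * fs) + 1L
      i1 <- round((events$onset[k] + spec$window[2]) * fs)
      if (i0 < 1 || i1 > n)
        stop(sprintf("event %d effect window outside recording", k))
      if (i1 <= i0) next
      tt <- (seq(i0, i1) - i0) / (i1 - i0)
      shape <- sin(pi * tt)^2
      if (!is.null(spec$osc_freq))
        shape <- shape * sin(2 * pi * spec$osc_freq * (seq(i0, i1) - i0) / fs)
      data[, i0:i1] <- data[, i0:i1] +
        spec$amplitude * outer(topo, shape)
    }
  }
  recording$data <- data
  recording
}
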