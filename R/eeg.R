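#' Offline preprocessing of a sleep recording
#'
#' Zero-phase (two-pass) Butterworth band-pass (default 0.5-30 Hz, applied
#' as separate high- and low-pass passes), linked-mastoid re-referencing
#' when a mastoid pair (M1/M2 or TP9/TP10) is present (otherwise a warning
#' is issued and the reference is left untouched), and neighbour-average
#' interpolation of user-declared bad channels.
#'
#' @param recording a `sleep_recording`.
#' @param l_freq,h_freq high-pass and low-pass corner frequencies (Hz);
#'   NULL disables the respective pass.
#' @param bad_channels character vector of channel labels to interpolate
#'   from their montage neighbours.
#' @param lp_order,hp_order Butterworth order per pass of the low-pass and
#'   high-pass (the high-pass stays at a lower order: high-order IIR
#'   designs at very low normalised corner frequencies are numerically
#'   fragile).
#' @return the preprocessed `sleep_recording`.
#' @export
preprocess <- function(recording, l_freq = 0.5, h_freq = 30,
                       bad_channels = NULL, lp_order = 4, hp_order = 2) {
  stopifnot(inherits(recording, "sleep_recording"))
  fs <- recording$sampling_rate
  data <- recording$data
  if (!is.null(bad_channels)) {
    if (length(bad_channels) >= nrow(data))
      stop("all channels marked bad")
    adj <- channel_adjacency(recording$montage)
    for (bc in bad_channels) {
      i <- match(bc, recording$channel_labels)
      if (is.na(i)) stop("bad channel ", bc, " not in recording")
      nb <- setdiff(which(adj[i, ]), match(bad_channels,
                                           recording$channel_labels))
      if (!length(nb)) stop("bad channel ", bc, " has no good neighbours")
      data[i, ] <- colMeans(data[nb, , drop = FALSE])
    }
  }
  if (!is.null(h_freq)) {
    lp <- signal::butter(lp_order, h_freq / (fs / 2), type = "low")
    data <- t(apply(data, 1, function(ch) signal::filtfilt(lp, ch)))
  }
  if (!is.null(l_freq)) {
    hp <- signal::butter(hp_order, l_freq / (fs / 2), type = "high")
    data <- t(apply(data, 1, function(ch) signal::filtfilt(hp, ch)))
  }
  mast <- intersect(c("M1", "M2", "TP9", "TP10"), recording$channel_labels)
  if (length(mast) >= 2) {
    mi <- match(mast[1:2], recording$channel_labels)
    ref <- colMeans(data[mi, , drop = FALSE])
    data <- sweep(data, 2, ref)
  } else {
    warning("no mastoid pair found; data left in original reference")
  }
  rownames(data) <- recording$channel_labels
  recording$data <- data
  recording
}

#' Cut cue-locked epochs from a recording
#'
#' One epoch per event over `window` seconds around onset; events whose
#' window is not fully covered by the recording are dropped with a message.
#'
#' @param recording a `sleep_recording`.
#' @param events data.frame with an `onset` column (s) plus any metadata
#'   columns (condition, sound_type, item, block, ...).
#' @param window c(start, end) seconds relative to cue onset; must cover 0.
#' @return object of class `epoch_set`: `data` (epochs x channels x
#'   samples array, uV), `times` (s relative to onset), `sampling_rate`,
#'   `channel_labels`, `metadata` (kept event rows, input order).
#' @export
epoch_recording <- function(recording, events, window = c(-1, 3)) {
  stopifnot(inherits(recording, "sleep_recording"))
  if (nrow(events) == 0) stop("no events to epoch")
  if (window[1] > 0 || window[2] < 0) stop("window must cover cue onset")
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  i_rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1L)
  on_i <- round(events$onset * fs) + 1L
  keep <- on_i + i_rel[1] >= 1 & on_i + i_rel[length(i_rel)] <= n
  if (!all(keep))
    message(sum(!keep), " event(s) dropped: epoch window not covered")
  if (!any(keep)) stop("no event fully covered by the recording")
  on_i <- on_i[keep]
  dat <- array(0, dim = c(length(on_i), nrow(recording$data), length(i_rel)))
  for (e in seq_along(on_i))
    dat[e, , ] <- recording$data[, on_i[e] + i_rel]
  structure(list(data = dat, times = i_rel / fs, sampling_rate = fs,
                 channel_labels = recording$channel_labels,
                 metadata = events[keep, , drop = FALSE]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g..%g s @ %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), x$sampling_rate))
  invisible(x)
}

#' Event-related potentials per condition cell
#'
#' Mean and SEM across epochs within each cell of the grouping columns
#' (default condition x sound_type). Requested cells without epochs are
#' reported as NULL entries and flagged.
#'
#' @param epochs an [epoch_recording()] result.
#' @param by metadata column names to group by; NULL pools all epochs.
#' @return object of class `erp_set`: named list `cells`, each with `mean`
#'   and `sem` (channels x samples) and `n`; plus `times`,
#'   `channel_labels`, `empty_cells`.
#' @export
compute_erp <- function(epochs, by = c("condition", "sound_type")) {
  stopifnot(inherits(epochs, "epoch_set"))
  md <- epochs$metadata
  key <- if (is.null(by)) rep("all", nrow(md)) else
    interaction(md[, by, drop = FALSE], drop = FALSE, sep = "/")
  cells <- list()
  empty <- character(0)
  for (lv in levels(factor(key))) {
    idx <- which(key == lv)
    if (!length(idx)) { empty <- c(empty, lv); cells[[lv]] <- NULL; next }
    sub <- epochs$data[idx, , , drop = FALSE]
    m <- apply(sub, c(2, 3), mean)
    s <- if (length(idx) > 1)
      apply(sub, c(2, 3), stats::sd) / sqrt(length(idx))
    else m * 0
    cells[[lv]] <- list(mean = m, sem = s, n = length(idx))
  }
  structure(list(cells = cells, times = epochs$times,
                 channel_labels = epochs$channel_labels,
                 empty_cells = empty),
            class = "erp_set")
}

# complex Morlet wavelet, sd_t = n_cycles / (2 pi f), support +/- 5 sd
morlet_wavelet <- function(freq, n_cycles, fs) {
  sd_t <- n_cycles / (2 * pi * freq)
  t <- seq(-5 * sd_t, 5 * sd_t, by = 1 / fs)
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sd_t^2))
  w / sqrt(sum(Mod(w)^2))  # unit energy
}

#' Morlet time-frequency decomposition
#'
#' Wavelet power per epoch, channel, frequency and requested time point.
#' Defaults follow the sleep-TMR analysis grid: 4-20 Hz in 0.5 Hz steps,
#' -1 to 2.4 s in 50 ms steps, wavelet width of at least 4 cycles, growing
#' with frequency (`n_cycles = max(4, f/2)`). Time bins whose wavelet
#' support extends past the epoch edge are flagged in the `edge_mask`
#' attribute rather than dropped.
#'
#' @param epochs an [epoch_recording()] result.
#' @param freqs frequencies of interest (Hz).
#' @param times output time grid (s relative to cue onset).
#' @param n_cycles wavelet width per frequency (recycled).
#' @param average if TRUE, average power over epochs.
#' @return object of class `tfr`: `power` (epochs x channels x freqs x
#'   times, or channels x freqs x times when averaged), `freqs`, `times`,
#'   `baseline_mode` = "raw", and attribute `edge_mask` (freqs x times).
#' @export
morlet_tfr <- function(epochs, freqs = seq(4, 20, by = 0.5),
                       times = seq(-1, 2.4, by = 0.05),
                       n_cycles = pmax(4, freqs / 2), average = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sampling_rate
  if (any(freqs >= fs / 2)) stop("requested frequency above Nyquist")
  if (min(times) < min(epochs$times) || max(times) > max(epochs$times))
    stop("requested times outside the epoch window")
  n_cycles <- rep_len(n_cycles, length(freqs))
  n_ep <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  n_s <- dim(epochs$data)[3]
  t_idx <- round((times - epochs$times[1]) * fs) + 1L
  pow <- array(0, dim = c(n_ep, n_ch, length(freqs), length(times)))
  edge <- matrix(FALSE, length(freqs), length(times))
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], n_cycles[fi], fs)
    half <- (length(w) - 1) / 2
    edge[fi, ] <- t_idx - half < 1 | t_idx + half > n_s
    nfft <- stats::nextn(n_s + length(w) - 1, 2)
    wf <- stats::fft(c(w, complex(real = rep(0, nfft - length(w)))))
    for (e in seq_len(n_ep)) for (ch in seq_len(n_ch)) {
      xf <- stats::fft(c(epochs$data[e, ch, ], rep(0, nfft - n_s)))
      conv <- stats::fft(xf * wf, inverse = TRUE) / nfft
      # centre of the wavelet aligns at lag half
      pow[e, ch, fi, ] <- Mod(conv[t_idx + half])^2
    }
  }
  if (average) pow <- apply(pow, c(2, 3, 4), mean)
  structure(list(power = pow, freqs = freqs, times = times,
                 channel_labels = epochs$channel_labels,
                 baseline_mode = "raw", edge_mask = edge),
            class = "tfr")
}

#' Baseline-normalise a TFR (relative change)
#'
#' Expresses power as `(P - mean_baseline) / mean_baseline` per channel and
#' frequency, with the baseline mean taken over the given pre-stimulus
#' window (default -1 to 0 s).
#'
#' @param tfr a [morlet_tfr()] result (raw power).
#' @param baseline c(start, end) seconds.
#' @return the `tfr` with normalised power and `baseline_mode` =
#'   "relative_change".
#' @export
baseline_normalize <- function(tfr, baseline = c(-1, 0)) {
  stopifnot(inherits(tfr, "tfr"))
  if (tfr$baseline_mode != "raw") stop("TFR already baseline-normalised")
  bidx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (!length(bidx)) stop("baseline window outside TFR times")
  nd <- length(dim(tfr$power))
  if (nd == 4) {
    base <- apply(tfr$power[, , , bidx, drop = FALSE], c(1, 2, 3), mean)
    if (any(base == 0)) stop("zero baseline power; cannot normalise")
    tfr$power <- sweep(tfr$power, c(1, 2, 3), base, "-")
    tfr$power <- sweep(tfr$power, c(1, 2, 3), base, "/")
  } else {
    base <- apply(tfr$power[, , bidx, drop = FALSE], c(1, 2), mean)
    if (any(base == 0)) stop("zero baseline power; cannot normalise")
    tfr$power <- sweep(tfr$power, c(1, 2), base, "-")
    tfr$power <- sweep(tfr$power, c(1, 2), base, "/")
  }
  tfr$baseline_mode <- "relative_change"
  tfr
}
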