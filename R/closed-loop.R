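#' Online slow-oscillation detector configuration
#'
#' Parameters of the replayed online detection path: the F3 signal is
#' band-pass filtered causally in the slow-wave range (0.5-4 Hz), and when
#' the (polarity-corrected) amplitude crosses -80 uV the negative half-wave
#' peak (trough) is located; the auditory cue is scheduled a fixed 500 ms
#' after the trough, subject to a minimum inter-trial pause of 4 s after
#' each 200 ms sound and an N3 stage gate. Down-phase targeting uses the
#' same detector on the polarity-inverted signal.
#'
#' @param detection_channel channel label used online.
#' @param band_low,band_high slow-wave band in Hz.
#' @param threshold detection threshold in uV (negative).
#' @param delay trough-to-cue delay in seconds.
#' @param min_iti minimum pause in seconds (see `iti_mode`).
#' @param allowed_stage sleep stage in which cueing is permitted.
#' @param confirm_window lookahead (s) of consecutively rising samples that
#'   confirms the trough.
#' @param sound_duration cue sound length in seconds.
#' @param iti_mode "offset": the pause runs from sound offset to next onset
#'   (onset-to-onset gap >= min_iti + sound_duration); "onset":
#'   onset-to-onset gap >= min_iti.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(detection_channel = "F3", band_low = 0.5,
                            band_high = 4, threshold = -80, delay = 0.5,
                            min_iti = 4, allowed_stage = "N3",
                            confirm_window = 0.02, sound_duration = 0.2,
                            iti_mode = c("offset", "onset")) {
  if (threshold >= 0) stop("threshold must be negative (uV)")
  if (delay <= 0) stop("delay must be positive")
  if (min_iti <= 0) stop("min_iti must be positive")
  if (band_low >= band_high) stop("band_low must be < band_high")
  structure(list(detection_channel = detection_channel, band_low = band_low,
                 band_high = band_high, threshold = threshold, delay = delay,
                 min_iti = min_iti, allowed_stage = allowed_stage,
                 confirm_window = confirm_window,
                 sound_duration = sound_duration,
                 iti_mode = match.arg(iti_mode)),
            class = "detector_config")
}

# Causal (forward-only) slow-wave band-pass: 1st-order Butterworth high-pass
# cascaded with a 2nd-order low-pass. The asymmetric orders keep the phase
# response near zero across the SO band (a symmetric band-pass centred at
# sqrt(0.5*4) ~ 1.4 Hz leads by 16-24 deg at 1 Hz, which would bias trough
# timing beyond the targeting tolerance).
causal_sw_filter <- function(x, fs, band_low, band_high) {
  if (band_high >= fs / 2) stop("band_high must be below Nyquist")
  hp <- signal::butter(1, band_low / (fs / 2), type = "high")
  lp <- signal::butter(2, band_high / (fs / 2), type = "low")
  as.numeric(signal::filter(lp, as.numeric(signal::filter(hp, x))))
}

#' Causal detection of SO negative half-wave peaks
#'
#' Runs the online trough detector over one channel: causal slow-wave
#' filtering, polarity correction, threshold crossing, and trough
#' confirmation once the filtered derivative has been positive for the
#' confirmation window. The trough time is the filtered-signal minimum of
#' the below-threshold excursion; the detection time (when the online system
#' can first act) is the end of the confirmation window.
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate Hz.
#' @param config a [detector_config()].
#' @param polarity +1 for up-phase targeting (true troughs), -1 for
#'   down-phase targeting (detects troughs of the inverted signal, i.e.
#'   positive peaks).
#' @return data.frame with `trough_time` and `detect_time` (s), ordered.
#' @export
detect_troughs <- function(x, fs, config, polarity = 1) {
  s <- polarity * causal_sw_filter(x, fs, config$band_low, config$band_high)
  below <- s < config$threshold
  if (!any(below)) return(data.frame(trough_time = numeric(0),
                                     detect_time = numeric(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  K <- max(1L, round(config$confirm_window * fs))
  # length of the consecutive-rising streak ending at each sample
  rising <- c(FALSE, diff(s) > 0)
  streak <- numeric(length(s))
  rr <- rle(rising)
  pos <- 1L
  for (j in seq_along(rr$lengths)) {
    idx <- pos:(pos + rr$lengths[j] - 1L)
    streak[idx] <- if (rr$values[j]) seq_len(rr$lengths[j]) else 0
    pos <- pos + rr$lengths[j]
  }
  n <- length(s)
  trough_i <- integer(0); detect_i <- integer(0)
  for (k in runs) {
    a <- starts[k]; b <- ends[k]
    ti <- a + which.min(s[a:b]) - 1L
    # confirmation: first sample after the trough with K rising samples
    hi <- min(n, b + round(0.5 * fs))
    win <- seq(ti + 1L, hi)
    if (length(win) == 0) next
    hit <- win[which(streak[win] >= K)[1]]
    if (is.na(hit)) next
    trough_i <- c(trough_i, ti)
    detect_i <- c(detect_i, hit)
  }
  data.frame(trough_time = (trough_i - 1L) / fs,
             detect_time = (detect_i - 1L) / fs)
}

#' Build a TMR cueing schedule
#'
#' Each block contains the four sound sets (Experimental-Up, Novel-Up,
#' Experimental-Down, Novel-Down) exactly once, in an order randomised per
#' block and counterbalanced across blocks (Latin squares over groups of 4
#' blocks); within a set the six sounds are always played in hierarchy
#' order A..F. Total planned cues = n_blocks x 4 x 6.
#'
#' @param n_blocks number of blocks (>= 0).
#' @param seed optional RNG seed.
#' @return data.frame of class `tmr_schedule` with columns `block`,
#'   `set_pos`, `condition`, `sound_type`, `item`.
#' @export
make_tmr_schedule <- function(n_blocks, seed = NULL) {
  if (n_blocks < 0) stop("n_blocks must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sets <- data.frame(condition = c("Up", "Up", "Down", "Down"),
                     sound_type = c("Experimental", "Novel",
                                    "Experimental", "Novel"),
                     stringsAsFactors = FALSE)
  out <- list()
  b <- 0L
  while (b < n_blocks) {
    take <- min(4L, n_blocks - b)
    base <- sample.int(4)
    square <- sapply(0:3, function(k) base[(seq_len(4) + k - 1) %% 4 + 1])
    square <- square[, sample.int(4), drop = FALSE]  # shuffle block order
    for (col in seq_len(take)) {
      b <- b + 1L
      ord <- square[, col]
      for (pos in seq_len(4)) {
        si <- ord[pos]
        out[[length(out) + 1]] <- data.frame(
          block = b, set_pos = pos, condition = sets$condition[si],
          sound_type = sets$sound_type[si], item = LETTERS[1:6],
          stringsAsFactors = FALSE)
      }
    }
  }
  sched <- if (length(out)) do.call(rbind, out) else
    data.frame(block = integer(0), set_pos = integer(0),
               condition = character(0), sound_type = character(0),
               item = character(0), stringsAsFactors = FALSE)
  class(sched) <- c("tmr_schedule", "data.frame")
  sched
}

# TRUE when a cue at time `onset` is inside the allowed stage and outside
# every arousal interval
stage_gate_open <- function(onset, recording, allowed_stage) {
  ep <- floor(onset / 30) + 1L
  if (ep > length(recording$hypnogram)) return(FALSE)
  if (recording$hypnogram[ep] != allowed_stage) return(FALSE)
  ar <- recording$arousals
  if (nrow(ar) && any(onset >= ar$start & onset <= ar$end)) return(FALSE)
  TRUE
}

#' Replay the closed-loop stimulation over a recording
#'
#' Processes the detection channel causally with the online trough detector
#' and walks the cueing schedule in order: the next pending sound's
#' condition selects the detector polarity (Up = troughs, Down = inverted
#' signal, i.e. positive peaks); a cue is delivered at trough + delay iff
#' the stage gate is open at cue onset, the inter-trial pause is satisfied,
#' and the sound fits inside the recording. Sets and blocks never
#' interleave; the undelivered schedule tail is returned as pending.
#'
#' @param recording a `sleep_recording` containing the detection channel.
#' @param schedule a [make_tmr_schedule()] data.frame (or any data.frame
#'   with `block`, `condition`, `sound_type`, `item`).
#' @param config a [detector_config()].
#' @return list with `events` (data.frame: `onset`, `condition`,
#'   `sound_type`, `item`, `block`, `detected_trough_time`) and `pending`
#'   (undelivered schedule rows).
#' @export
run_closed_loop <- function(recording, schedule, config = detector_config()) {
  stopifnot(inherits(recording, "sleep_recording"))
  if (nrow(schedule) == 0) stop("schedule is empty")
  ch <- match(config$detection_channel, recording$channel_labels)
  if (is.na(ch)) stop("detection channel ", config$detection_channel,
                      " not in recording")
  fs <- recording$sampling_rate
  x <- recording$data[ch, ]
  dur <- length(x) / fs
  tr_up <- detect_troughs(x, fs, config, polarity = 1)
  tr_dn <- detect_troughs(x, fs, config, polarity = -1)
  gap <- if (config$iti_mode == "offset")
    config$min_iti + config$sound_duration else config$min_iti
  last_onset <- -Inf
  last_trough <- -Inf
  ev <- vector("list", nrow(schedule))
  delivered <- 0L
  for (i in seq_len(nrow(schedule))) {
    tr <- if (schedule$condition[i] == "Up") tr_up else tr_dn
    cand <- which(tr$trough_time > last_trough &
                    tr$trough_time + config$delay >= last_onset + gap)
    onset <- NA_real_
    for (j in cand) {
      o <- tr$trough_time[j] + config$delay
      if (o + config$sound_duration > dur) break
      if (o < tr$detect_time[j]) next  # cannot act before confirmation
      if (!stage_gate_open(o, recording, config$allowed_stage)) next
      onset <- o; last_trough <- tr$trough_time[j]; break
    }
    if (is.na(onset)) break
    last_onset <- onset
    delivered <- i
    ev[[i]] <- data.frame(onset = onset,
                          condition = schedule$condition[i],
                          sound_type = schedule$sound_type[i],
                          item = schedule$item[i],
                          block = schedule$block[i],
                          detected_trough_time = last_trough,
                          stringsAsFactors = FALSE)
  }
  events <- if (delivered > 0) do.call(rbind, ev[seq_len(delivered)]) else
    data.frame(onset = numeric(0), condition = character(0),
               sound_type = character(0), item = character(0),
               block = integer(0), detected_trough_time = numeric(0),
               stringsAsFactors = FALSE)
  pending <- schedule[seq_len(nrow(schedule)) > delivered, , drop = FALSE]
  list(events = events, pending = pending)
}

#' Summarise cue delivery
#'
#' @param events delivered-cue data.frame from [run_closed_loop()].
#' @return list with `counts` (condition x sound_type table), `n_total`,
#'   `min_gap` and `mean_gap` between consecutive onsets (NA when < 2 cues).
#' @export
summarize_delivery <- function(events) {
  counts <- matrix(0L, 2, 2, dimnames = list(c("Up", "Down"),
                                             c("Experimental", "Novel")))
  if (nrow(events)) {
    tab <- table(factor(events$condition, c("Up", "Down")),
                 factor(events$sound_type, c("Experimental", "Novel")))
    counts[] <- as.integer(tab)
  }
  gaps <- if (nrow(events) >= 2) diff(sort(events$onset)) else numeric(0)
  list(counts = counts, n_total = nrow(events),
       min_gap = if (length(gaps)) min(gaps) else NA_real_,
       mean_gap = if (length(gaps)) mean(gaps) else NA_real_)
}
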