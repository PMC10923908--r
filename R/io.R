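#' Write / read cue events as TSV
#'
#' Columns: onset, condition, sound_type, item, block,
#' detected_trough_time.
#'
#' @param events delivered-cue data.frame ([run_closed_loop()]).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a hypnogram as TSV (onset, duration, stage)
#'
#' One row per 30-s scoring epoch.
#'
#' @param recording a `sleep_recording` (or a character stage vector).
#' @param path file path.
#' @export
write_hypnogram_tsv <- function(recording, path) {
  stages <- if (inherits(recording, "sleep_recording"))
    recording$hypnogram else recording
  df <- data.frame(onset = (seq_along(stages) - 1) * 30,
                   duration = 30, stage = stages)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_tsv
#' @export
read_hypnogram_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "stage") %in% names(df)))
    stop("hypnogram TSV needs columns onset, duration, stage")
  df
}

#' Write / read a behavioural response table as TSV
#'
#' @param responses data.frame (see [score_behaviour()] for the expected
#'   columns).
#' @param path file path.
#' @export
write_behaviour_tsv <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour_tsv
#' @export
read_behaviour_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Save / load a simulation configuration as YAML
#'
#' @param config a [sim_config()] (or any plain list).
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML configs")
  cfg <- unclass(config)
  cfg$stage_plan <- if (!is.null(cfg$stage_plan)) as.list(cfg$stage_plan)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML configs")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$stage_plan))
    cfg$stage_plan <- as.data.frame(cfg$stage_plan,
                                    stringsAsFactors = FALSE)
  do.call(sim_config, cfg)
}
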