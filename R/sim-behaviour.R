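#' Configuration for the behavioural simulator
#'
#' Defines the true per-cell accuracies of a simulated cohort on the
#' transitive-inference task: one probability per condition (Up / Down /
#' Control) x session (1..3) x pair class (premise, deg1, deg2, anchor),
#' plus a subject-level random effect on the logit scale.
#'
#' @param n_subjects number of simulated subjects.
#' @param true_accuracy data.frame with columns `condition`, `session`,
#'   `pair_class`, `p` (probability in (0,1)). Cells absent from the table
#'   are not simulated.
#' @param subject_effect_sd SD of the per-subject random intercept (logit
#'   units) shared across all cells of a subject.
#' @param trials_per_cell number of Bernoulli trials per cell (>= 1).
#' @param seed integer RNG seed.
#' @return object of class `behaviour_sim_config`.
#' @export
behaviour_sim_config <- function(n_subjects, true_accuracy,
                                 subject_effect_sd = 0.3,
                                 trials_per_cell = 8, seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!is.data.frame(true_accuracy) || nrow(true_accuracy) == 0)
    stop("true_accuracy must be a non-empty data.frame")
  if (!all(c("condition", "session", "pair_class", "p") %in% names(true_accuracy)))
    stop("true_accuracy needs columns condition, session, pair_class, p")
  if (any(true_accuracy$p <= 0 | true_accuracy$p >= 1))
    stop("probabilities must be in (0,1)")
  if (trials_per_cell < 1) stop("trials_per_cell must be >= 1")
  structure(list(n_subjects = n_subjects, true_accuracy = true_accuracy,
                 subject_effect_sd = subject_effect_sd,
                 trials_per_cell = trials_per_cell, seed = seed),
            class = "behaviour_sim_config")
}

#' Default accuracy table for a simulated cohort
#'
#' A plausible next-morning pattern for the task: solid premise knowledge in
#' all conditions, a benefit of up-phase cueing on the most distant (2nd
#' degree) inferences at session 2, down-phase performance below chance at
#' session 2 recovering by session 3, and near-ceiling anchor pairs.
#'
#' @return data.frame usable as `true_accuracy` in [behaviour_sim_config()].
#' @export
default_accuracy_table <- function() {
  grid <- expand.grid(condition = c("Up", "Down", "Control"),
                      session = 1:3,
                      pair_class = c("premise", "deg1", "deg2", "anchor"),
                      stringsAsFactors = FALSE)
  p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p[i] <- switch(g$pair_class,
      premise = if (g$session == 3) 0.68 else
        c(Up = 0.796, Down = 0.747, Control = 0.792)[[g$condition]],
      deg1 = if (g$session == 2 && g$condition == "Down") 0.50 else 0.62,
      deg2 = if (g$session == 2) c(Up = 0.72, Down = 0.46, Control = 0.55)[[g$condition]]
             else c(Up = 0.62, Down = 0.586, Control = 0.60)[[g$condition]],
      anchor = 0.85)
  }
  grid$p <- p
  # premise pairs are not split by degree until learned; session 1 has no
  # inference or anchor trials
  grid[!(grid$session == 1 & grid$pair_class != "premise"), ]
}

#' Simulate a behavioural response table
#'
#' Draws per-trial correctness as Bernoulli with success probability
#' `plogis(qlogis(p_cell) + b_subject)`, where `b_subject` is a normal
#' random intercept shared across cells within subject.
#'
#' @param config a [behaviour_sim_config()].
#' @return data.frame with columns `subject`, `condition`, `session`,
#'   `pair_class`, `trial`, `correct` (0/1).
#' @export
generate_behaviour <- function(config) {
  stopifnot(inherits(config, "behaviour_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ta <- config$true_accuracy
  b <- stats::rnorm(config$n_subjects, 0, config$subject_effect_sd)
  m <- config$trials_per_cell
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    p_s <- stats::plogis(stats::qlogis(ta$p) + b[s])
    correct <- stats::rbinom(nrow(ta) * m, 1, rep(p_s, each = m))
    out[[s]] <- data.frame(subject = s,
                           condition = rep(ta$condition, each = m),
                           session = rep(ta$session, each = m),
                           pair_class = rep(ta$pair_class, each = m),
                           trial = rep(seq_len(m), times = nrow(ta)),
                           correct = correct,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
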