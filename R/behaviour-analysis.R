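#' Test a behavioural cell against chance level
#'
#' One-sample test of per-subject accuracies against chance (default 50%).
#' The parametric/nonparametric choice is gated on a Shapiro-Wilk
#' normality check at alpha = 0.05: Student's t-test when normality is not
#' rejected, Wilcoxon signed-rank otherwise. Constant input at chance is
#' flagged degenerate.
#'
#' @param x per-subject accuracies (same scale as `chance`).
#' @param chance chance level (0.5 for proportions, 50 for percent).
#' @return list with `statistic`, `p`, `method`, `normality_p`,
#'   `degenerate`.
#' @export
chance_level_test <- function(x, chance = 0.5) {
  if (length(x) < 3) stop("need at least 3 subjects")
  if (all(x == chance))
    return(list(statistic = 0, p = 1, method = "degenerate",
                normality_p = NA_real_, degenerate = TRUE))
  sw <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  if (sw >= 0.05) {
    tt <- stats::t.test(x, mu = chance)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = "t-test", normality_p = sw, degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = chance, exact = FALSE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "wilcoxon", normality_p = sw, degenerate = FALSE)
  }
}

#' Correlate decoding performance with behaviour (bootstrap inference)
#'
#' Pearson correlation between per-subject decoding scores (cluster mean or
#' peak) and a behavioural cell, with a percentile bootstrap confidence
#' interval over subject resampling and a permutation p-value (index
#' permutation under independence). The reported corrected p applies the
#' first Holm step for the declared family of tested classifier/metric x
#' behaviour combinations (`p * family_size`, capped at 1), which is
#' conservative and never below the raw p.
#'
#' @param scores per-subject decoding scores.
#' @param accuracies per-subject behavioural accuracies (paired).
#' @param n_boot bootstrap/permutation draws.
#' @param seed RNG seed.
#' @param family_size number of tests in the correction family.
#' @param conf confidence level of the percentile interval.
#' @return object of class `correlation_result`: `r`, `ci`, `p_raw`,
#'   `p_corrected`, `n`, `method`.
#' @export
correlate_decoding_behaviour <- function(scores, accuracies, n_boot = 2000,
                                         seed = NULL, family_size = 1,
                                         conf = 0.95) {
  if (length(scores) != length(accuracies)) stop("inputs must be paired")
  n <- length(scores)
  if (n < 5) stop("need at least 5 paired observations")
  if (anyNA(scores) || anyNA(accuracies)) stop("NA in input")
  if (stats::sd(scores) == 0 || stats::sd(accuracies) == 0)
    stop("zero-variance input")
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(scores, accuracies)
  boot_r <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    if (stats::sd(scores[idx]) == 0 || stats::sd(accuracies[idx]) == 0)
      return(NA_real_)
    stats::cor(scores[idx], accuracies[idx])
  }, numeric(1))
  ci <- stats::quantile(boot_r, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  perm_r <- vapply(seq_len(n_boot), function(b)
    stats::cor(scores, accuracies[sample.int(n)]), numeric(1))
  p_raw <- (1 + sum(abs(perm_r) >= abs(r))) / (n_boot + 1)
  structure(list(r = r, ci = ci, p_raw = p_raw,
                 p_corrected = min(1, p_raw * family_size), n = n,
                 method = paste0("pearson + percentile bootstrap (",
                                 n_boot, " draws), permutation p, ",
                                 "Holm bound x", family_size)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("R = %.3f [%.3f, %.3f], p = %.4f (corrected %.4f), n = %d\n",
              x$r, x$ci[1], x$ci[2], x$p_raw, x$p_corrected, x$n))
  invisible(x)
}

#' Holm correction across a family of correlation p-values
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values (stats::p.adjust, method "holm").
#' @export
correct_family <- function(p) stats::p.adjust(p, method = "holm")
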