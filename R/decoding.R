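#' Decoding configuration
#'
#' Settings for per-timepoint multivariate classification of Experimental
#' vs Novel cue epochs: stratified k-fold cross-validation with
#' repetitions, within-fold z-scoring and PCA (both fit on training data
#' only), LDA and/or linear SVM, and ACC/AUC metrics.
#'
#' @param classifiers subset of c("lda", "svm").
#' @param metrics subset of c("acc", "auc").
#' @param folds number of CV folds (>= 2; analysis default 5).
#' @param repetitions number of CV repetitions (>= 1; default 2).
#' @param pca_components retained principal components (<= feature count).
#' @param feature_band zero-phase band-pass (Hz) applied to epochs before
#'   decoding; NULL disables.
#' @param time_decim keep every `time_decim`-th sample of the epoch grid
#'   (1 = native resolution).
#' @param seed RNG seed for fold assignment.
#' @return object of class `decoding_config`.
#' @export
decoding_config <- function(classifiers = c("lda", "svm"),
                            metrics = c("acc", "auc"),
                            folds = 5, repetitions = 2,
                            pca_components = 20,
                            feature_band = c(4, 20),
                            time_decim = 1, seed = NULL) {
  classifiers <- match.arg(classifiers, c("lda", "svm"), several.ok = TRUE)
  metrics <- match.arg(metrics, c("acc", "auc"), several.ok = TRUE)
  if (folds < 2) stop("folds must be >= 2")
  if (repetitions < 1) stop("repetitions must be >= 1")
  structure(list(classifiers = classifiers, metrics = metrics,
                 folds = folds, repetitions = repetitions,
                 pca_components = pca_components,
                 feature_band = feature_band, time_decim = time_decim,
                 seed = seed),
            class = "decoding_config")
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' @param scores decision scores, larger = more evidence for the positive
#'   class.
#' @param labels logical or 0/1 vector (TRUE/1 = positive class).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment, one integer fold id per trial
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

#' Per-timepoint decoding of a two-class epoch set
#'
#' For every time point on the (optionally decimated) epoch grid, the
#' channel vector at that sample is the feature; each cross-validation
#' training fold supplies the z-scoring parameters and the PCA basis, which
#' are then applied to the held-out fold before classification. Performance
#' is averaged over folds and repetitions (accuracy is fold-size
#' weighted; AUC is computed from pooled held-out decision scores per
#' repetition).
#'
#' @param epochs an [epoch_recording()] result whose metadata contains the
#'   label column.
#' @param config a [decoding_config()].
#' @param label_col metadata column holding the two class labels.
#' @param positive_class label treated as positive for AUC; default the
#'   first sorted level.
#' @return object of class `decoding_series`: `performance` array
#'   (classifier x metric x time, values in [0, 1]), `times`, `n_per_class`,
#'   `chance` = 0.5.
#' @export
decode_timecourse <- function(epochs, config = decoding_config(),
                              label_col = "sound_type",
                              positive_class = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  y <- as.character(epochs$metadata[[label_col]])
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("need exactly two classes, got ",
                             length(lev))
  if (is.null(positive_class)) positive_class <- lev[1]
  pos <- y == positive_class
  tab <- table(y)
  if (any(tab < config$folds))
    stop("class with fewer trials (", min(tab), ") than folds (",
         config$folds, ")")
  n_ch <- dim(epochs$data)[2]
  if (config$pca_components > n_ch)
    stop("pca_components exceeds the number of features")
  if (!is.null(config$seed)) set.seed(config$seed)

  dat <- epochs$data
  if (!is.null(config$feature_band)) {
    fs <- epochs$sampling_rate
    bf <- signal::butter(2, config$feature_band / (fs / 2), type = "pass")
    for (e in seq_len(dim(dat)[1])) for (ch in seq_len(n_ch))
      dat[e, ch, ] <- signal::filtfilt(bf, dat[e, ch, ])
  }
  t_idx <- seq(1, dim(dat)[3], by = config$time_decim)
  times <- epochs$times[t_idx]
  ncl <- length(config$classifiers); nme <- length(config$metrics)
  perf <- array(0, dim = c(ncl, nme, length(t_idx)),
                dimnames = list(config$classifiers, config$metrics, NULL))
  folds_per_rep <- lapply(seq_len(config$repetitions), function(r)
    stratified_folds(y, config$folds))
  n_trials <- length(y)

  for (ti in seq_along(t_idx)) {
    X <- dat[, , t_idx[ti]]  # trials x channels
    acc_tot <- matrix(0, ncl, config$repetitions)
    auc_tot <- matrix(0, ncl, config$repetitions)
    for (r in seq_len(config$repetitions)) {
      fold <- folds_per_rep[[r]]
      scores <- matrix(NA_real_, ncl, n_trials)
      pred_ok <- matrix(NA, ncl, n_trials)
      for (k in seq_len(config$folds)) {
        tr <- fold != k; te <- !tr
        mu <- colMeans(X[tr, , drop = FALSE])
        sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sg[sg < .Machine$double.eps] <- 1
        Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
        Zte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
        npc <- min(config$pca_components, ncol(Ztr), sum(tr) - 1)
        pc <- svd(Ztr, nu = 0, nv = npc)
        Ptr <- Ztr %*% pc$v
        Pte <- Zte %*% pc$v
        ytr <- factor(pos[tr], levels = c(FALSE, TRUE))
        for (ci in seq_along(config$classifiers)) {
          if (config$classifiers[ci] == "lda") {
            fit <- suppressWarnings(MASS::lda(Ptr, grouping = ytr))
            pr <- stats::predict(fit, Pte)
            sc <- pr$posterior[, "TRUE"]
            hit <- (pr$class == "TRUE") == pos[te]
          } else {
            fit <- e1071::svm(Ptr, ytr, kernel = "linear", scale = FALSE)
            pr <- stats::predict(fit, Pte, decision.values = TRUE)
            dv <- drop(attr(pr, "decision.values"))
            # orient decision values toward the positive class
            sc <- if (grepl("^TRUE", colnames(attr(pr, "decision.values"))[1]))
              dv else -dv
            hit <- (pr == "TRUE") == pos[te]
          }
          scores[ci, te] <- sc
          pred_ok[ci, te] <- hit
        }
      }
      for (ci in seq_len(ncl)) {
        acc_tot[ci, r] <- mean(pred_ok[ci, ])
        auc_tot[ci, r] <- auc_rank(scores[ci, ], pos)
      }
    }
    for (ci in seq_len(ncl)) for (mi in seq_len(nme)) {
      perf[ci, mi, ti] <- if (config$metrics[mi] == "acc")
        mean(acc_tot[ci, ]) else mean(auc_tot[ci, ])
    }
  }
  structure(list(performance = perf, times = times,
                 n_per_class = as.integer(tab), chance = 0.5,
                 classifiers = config$classifiers,
                 metrics = config$metrics),
            class = "decoding_series")
}

#' @export
print.decoding_series <- function(x, ...) {
  cat(sprintf("<decoding_series> %s x %s x %d time points; n/class = %s\n",
              paste(x$classifiers, collapse = ","),
              paste(x$metrics, collapse = ","),
              dim(x$performance)[3],
              paste(x$n_per_class, collapse = "/")))
  invisible(x)
}

#' Group-level decoding significance against chance
#'
#' Between-subject cluster permutation test of per-timepoint decoding
#' performance against the 0.5 chance level; delegates to
#' [cluster_test_timecourse()].
#'
#' @param series_list list of [decode_timecourse()] results (one per
#'   subject), or a subjects x time matrix of performance values.
#' @param classifier,metric which performance series to extract when a
#'   list is given.
#' @param config a [cluster_config()].
#' @return a `cluster_result` (see [cluster_test_timecourse()]).
#' @export
group_decoding_test <- function(series_list, classifier = "lda",
                                metric = "auc",
                                config = cluster_config()) {
  X <- if (is.matrix(series_list)) series_list else {
    if (length(series_list) < 2) stop("need at least 2 subjects")
    do.call(rbind, lapply(series_list, function(s)
      s$performance[classifier, metric, ]))
  }
  if (nrow(X) < 2) stop("need at least 2 subjects")
  cluster_test_timecourse(X, null_value = 0.5, config = config)
}

#' Per-subject performance within a cluster
#'
#' @param X subjects x time matrix of decoding performance.
#' @param cluster_bins integer vector of time-bin indices forming the
#'   cluster.
#' @return data.frame with `subject`, `mean`, `peak`.
#' @export
cluster_scores <- function(X, cluster_bins) {
  if (!length(cluster_bins)) stop("empty cluster")
  sub <- X[, cluster_bins, drop = FALSE]
  data.frame(subject = seq_len(nrow(X)),
             mean = rowMeans(sub),
             peak = apply(sub, 1, max))
}
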