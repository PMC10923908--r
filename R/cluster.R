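#' Cluster permutation test configuration
#'
#' @param n_permutations number of permutations (>= 100; analysis default
#'   2000).
#' @param alpha_cluster_forming per-bin two-tailed alpha for the
#'   cluster-forming threshold (t-distribution quantile at df =
#'   n_subjects - 1).
#' @param alpha_cluster final cluster-level alpha.
#' @param seed RNG seed for the permutation scheme.
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(n_permutations = 2000,
                           alpha_cluster_forming = 0.05,
                           alpha_cluster = 0.05, seed = NULL) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (alpha_cluster_forming <= 0 || alpha_cluster_forming >= 1 ||
      alpha_cluster <= 0 || alpha_cluster >= 1)
    stop("alphas must be in (0,1)")
  structure(list(n_permutations = n_permutations,
                 alpha_cluster_forming = alpha_cluster_forming,
                 alpha_cluster = alpha_cluster, seed = seed),
            class = "cluster_config")
}

# one-sample t statistics per column given data matrix (subjects x bins)
col_tstats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  m / sqrt(pmax(v, .Machine$double.eps) / n)
}

# contiguous 1-D clusters of a thresholded t vector, split by sign
find_clusters_1d <- function(t, thr) {
  lab <- integer(length(t))
  lab[t > thr] <- 1L
  lab[t < -thr] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (!length(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      sign = integer(0), mass = numeric(0)))
  data.frame(start = starts[keep], end = ends[keep], sign = r$values[keep],
             mass = vapply(keep, function(k)
               sum(t[starts[k]:ends[k]]), numeric(1)))
}

max_cluster_mass_1d <- function(t, thr) {
  cl <- find_clusters_1d(t, thr)
  if (!nrow(cl)) 0 else max(abs(cl$mass))
}

#' Cluster-based permutation test for a time course
#'
#' One-sample (or paired-difference) cluster test across subjects: per-bin
#' one-sample t against `null_value`, cluster-forming threshold at the
#' two-tailed t quantile, cluster mass = sum of t within contiguous
#' same-sign runs, and a max-statistic null distribution built by random
#' sign flipping of subject deviations (equivalently, condition swapping
#' for paired differences).
#'
#' @param X subjects x bins numeric matrix (per-subject series, or paired
#'   differences).
#' @param null_value value under the null hypothesis (0 for differences,
#'   0.5 for AUC against chance).
#' @param config a [cluster_config()].
#' @return object of class `cluster_result`: data.frame with `start`,
#'   `end` (bin indices), `sign`, `mass`, `p`; attributes `t` (observed
#'   per-bin t), `threshold`, `alpha_cluster`.
#' @export
cluster_test_timecourse <- function(X, null_value = 0,
                                    config = cluster_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 subjects")
  if (anyNA(X)) stop("NA values in input")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(X); nb <- ncol(X)
  D <- X - null_value
  thr <- stats::qt(1 - config$alpha_cluster_forming / 2, df = n - 1)
  t_obs <- col_tstats(D)
  clusters <- find_clusters_1d(t_obs, thr)
  np <- config$n_permutations
  # sign-flip null: t is computable in closed form because the column sum
  # of squares is invariant under sign flips
  S <- matrix(sample(c(-1, 1), np * n, replace = TRUE), np, n)
  M <- S %*% D / n
  SS <- colSums(D^2)
  Vp <- sweep(-n * M^2, 2, SS, "+") / (n - 1)
  Tp <- M / sqrt(pmax(Vp, .Machine$double.eps) / n)
  null_max <- vapply(seq_len(np), function(i)
    max_cluster_mass_1d(Tp[i, ], thr), numeric(1))
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (np + 1), numeric(1))
  } else clusters$p <- numeric(0)
  structure(clusters, class = c("cluster_result", "data.frame"),
            t = t_obs, threshold = thr,
            alpha_cluster = config$alpha_cluster)
}

#' @export
print.cluster_result <- function(x, ...) {
  alpha <- attr(x, "alpha_cluster")
  if (!nrow(x)) {
    cat("<cluster_result> no suprathreshold clusters\n")
    return(invisible(x))
  }
  cat(sprintf("<cluster_result> %d cluster(s), %d significant at alpha = %g\n",
              nrow(x), sum(x$p < alpha), alpha))
  print.data.frame(x)
  invisible(x)
}

# connected components of a logical mask over (channel, freq, time) bins;
# neighbours: +/-1 freq, +/-1 time (same channel) and adjacent channels
# (same freq/time). Returns a list of index matrices (ch, f, t).
components_3d <- function(mask, adjacency) {
  dm <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  comp <- integer(length(mask))
  nb_list <- lapply(seq_len(dm[1]), function(ch) which(adjacency[ch, ]))
  lin <- function(c0, f0, t0) c0 + dm[1] * (f0 - 1 + dm[2] * (t0 - 1))
  cur <- 0L
  out <- list()
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      v0 <- v - 1L
      c0 <- v0 %% dm[1] + 1L
      f0 <- (v0 %/% dm[1]) %% dm[2] + 1L
      t0 <- v0 %/% (dm[1] * dm[2]) + 1L
      cand <- integer(0)
      if (f0 > 1) cand <- c(cand, lin(c0, f0 - 1L, t0))
      if (f0 < dm[2]) cand <- c(cand, lin(c0, f0 + 1L, t0))
      if (t0 > 1) cand <- c(cand, lin(c0, f0, t0 - 1L))
      if (t0 < dm[3]) cand <- c(cand, lin(c0, f0, t0 + 1L))
      if (length(nb_list[[c0]]))
        cand <- c(cand, lin(nb_list[[c0]], f0, t0))
      cand <- cand[mask[cand] & comp[cand] == 0L]
      comp[cand] <- cur
      queue <- c(queue, cand)
    }
    out[[cur]] <- members
  }
  out
}

max_cluster_mass_3d <- function(tarr, thr, adjacency) {
  best <- 0
  for (sgn in c(1, -1)) {
    comps <- components_3d(sgn * tarr > thr, adjacency)
    for (m in comps) best <- max(best, abs(sum(tarr[m])))
  }
  best
}

#' Cluster-based permutation test for channel x frequency x time arrays
#'
#' Paired comparison of two conditions (e.g. Experimental vs Novel TFRs):
#' per-bin paired t over subjects, clusters contiguous in frequency and
#' time and connected across neighbouring channels, permutation by
#' within-subject condition swapping (sign flips of the paired
#' differences), max-statistic correction. The test can be restricted to a
#' post-cue time window.
#'
#' @param A,B subjects x channels x freqs x times arrays of equal shape.
#' @param adjacency logical channel adjacency matrix
#'   ([channel_adjacency()]).
#' @param config a [cluster_config()].
#' @param time_window optional c(start, end) restriction, in the units of
#'   `times`.
#' @param times time axis of the arrays (needed with `time_window`).
#' @return object of class `cluster_result_3d`: list of clusters, each
#'   with `bins` (matrix of ch/f/t indices), `mass`, `sign`, `p`; plus
#'   `t` array and `threshold`.
#' @export
cluster_test_tfr <- function(A, B, adjacency, config = cluster_config(),
                             time_window = NULL, times = NULL) {
  if (!identical(dim(A), dim(B))) stop("A and B shapes differ")
  if (length(dim(A)) != 4) stop("expected subjects x channels x freqs x times")
  if (nrow(adjacency) != dim(A)[2]) stop("adjacency does not cover channels")
  if (!is.null(config$seed)) set.seed(config$seed)
  tsel <- seq_len(dim(A)[4])
  if (!is.null(time_window)) {
    if (is.null(times)) stop("times needed with time_window")
    tsel <- which(times >= time_window[1] & times <= time_window[2])
  }
  D <- A[, , , tsel, drop = FALSE] - B[, , , tsel, drop = FALSE]
  n <- dim(D)[1]
  if (n < 2) stop("need at least 2 subjects")
  dm <- dim(D)[2:4]
  Dm <- matrix(D, nrow = n)  # subjects x (ch*f*t)
  thr <- stats::qt(1 - config$alpha_cluster_forming / 2, df = n - 1)
  t_obs <- array(col_tstats(Dm), dim = dm)
  np <- config$n_permutations
  S <- matrix(sample(c(-1, 1), np * n, replace = TRUE), np, n)
  M <- S %*% Dm / n
  SS <- colSums(Dm^2)
  Vp <- sweep(-n * M^2, 2, SS, "+") / (n - 1)
  Tp <- M / sqrt(pmax(Vp, .Machine$double.eps) / n)
  null_max <- vapply(seq_len(np), function(i)
    max_cluster_mass_3d(array(Tp[i, ], dim = dm), thr, adjacency),
    numeric(1))
  clusters <- list()
  for (sgn in c(1, -1)) {
    comps <- components_3d(sgn * t_obs > thr, adjacency)
    for (m in comps) {
      mass <- sum(t_obs[m])
      clusters[[length(clusters) + 1]] <- list(
        bins = arrayInd(m, dm), mass = mass, sign = sgn,
        p = (1 + sum(null_max >= abs(mass))) / (np + 1))
    }
  }
  structure(list(clusters = clusters, t = t_obs, threshold = thr,
                 time_sel = tsel,
                 alpha_cluster = config$alpha_cluster),
            class = "cluster_result_3d")
}

#' @export
print.cluster_result_3d <- function(x, ...) {
  cat(sprintf("<cluster_result_3d> %d cluster(s)\n", length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: sign %+d, %d bins, mass %.1f, p = %.4f\n",
                i, cl$sign, nrow(cl$bins), cl$mass, cl$p))
  }
  invisible(x)
}
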