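#' Standard 60-channel scalp montage
#'
#' Approximate 2-D projected positions (head radius = 1) for a 60-channel
#' 10-10 scalp layout, optionally extended with the mastoid pair M1/M2 used
#' for offline re-referencing. Positions are schematic: they carry the
#' left/right and anterior/posterior structure needed for frontal-weighted
#' source mixing and distance-based channel adjacency, not digitised
#' electrode coordinates.
#'
#' @param n_channels number of scalp channels to return (<= 60); the first
#'   `n_channels` labels of the full layout, which always include F3, Fz,
#'   F4 and Cz.
#' @param include_mastoids if TRUE, append M1/M2 below the ears.
#' @return data.frame with columns `label`, `x` (left - / right +), `y`
#'   (posterior - / anterior +).
#' @export
standard_montage <- function(n_channels = 60, include_mastoids = FALSE) {
  rows <- list(
    list(y = 0.95, labs = c("Fp1", "Fpz", "Fp2"), xs = c(-0.31, 0, 0.31)),
    list(y = 0.82, labs = c("AF7", "AF3", "AF4", "AF8"),
         xs = c(-0.59, -0.33, 0.33, 0.59)),
    list(y = 0.55, labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
         xs = c(-0.81, -0.63, -0.43, -0.22, 0, 0.22, 0.43, 0.63, 0.81)),
    list(y = 0.28, labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
         xs = c(-0.95, -0.72, -0.48, -0.24, 0, 0.24, 0.48, 0.72, 0.95)),
    list(y = 0.00, labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
         xs = c(-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75, 1)),
    list(y = -0.28, labs = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
         xs = c(-0.95, -0.72, -0.48, -0.24, 0, 0.24, 0.48, 0.72, 0.95)),
    list(y = -0.55, labs = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
         xs = c(-0.81, -0.63, -0.43, -0.22, 0, 0.22, 0.43, 0.63, 0.81)),
    list(y = -0.82, labs = c("PO7", "PO3", "POz", "PO4", "PO8"),
         xs = c(-0.59, -0.33, 0, 0.33, 0.59)),
    list(y = -0.95, labs = c("O1", "Oz", "O2"), xs = c(-0.31, 0, 0.31))
  )
  lab <- unlist(lapply(rows, `[[`, "labs"))
  x <- unlist(lapply(rows, `[[`, "xs"))
  y <- unlist(lapply(rows, function(r) rep(r$y, length(r$labs))))
  m <- data.frame(label = lab, x = x, y = y, stringsAsFactors = FALSE)
  stopifnot(nrow(m) == 60)
  if (n_channels < 1 || n_channels > 60)
    stop("n_channels must be between 1 and 60")
  if (n_channels < 60) {
    # keep the detection-relevant channels first, then fill by layout order
    core <- c("F3", "Fz", "F4", "Cz")
    keep <- c(core, setdiff(m$label, core))[seq_len(n_channels)]
    m <- m[match(keep, m$label), , drop = FALSE]
  }
  if (include_mastoids) {
    m <- rbind(m, data.frame(label = c("M1", "M2"),
                             x = c(-1.05, 1.05), y = c(-0.1, -0.1)))
  }
  rownames(m) <- NULL
  m
}

#' Distance-based channel adjacency graph
#'
#' Builds a symmetric channel neighbourhood graph by thresholding pairwise
#' Euclidean distance between montage positions, as needed by the
#' channel-aware cluster permutation test.
#'
#' @param montage data.frame with `label`, `x`, `y` (see [standard_montage()]).
#' @param threshold neighbour distance cutoff in head-radius units.
#' @return logical adjacency matrix with channel labels as dimnames and an
#'   `isolated` attribute listing channels without neighbours.
#' @export
channel_adjacency <- function(montage, threshold = 0.4) {
  if (!all(c("label", "x", "y") %in% names(montage)))
    stop("montage must have columns label, x, y")
  if (nrow(montage) < 2) stop("need at least 2 channels")
  if (anyNA(montage$x) || anyNA(montage$y))
    stop("montage has missing coordinates")
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- d <= threshold & d > 0
  dimnames(adj) <- list(montage$label, montage$label)
  iso <- montage$label[rowSums(adj) == 0]
  if (length(iso)) attr(adj, "isolated") <- iso
  adj
}
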