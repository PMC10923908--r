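#' Instantaneous slow-wave phase via the analytic signal
#'
#' Two-pass (zero-phase) Butterworth band-pass followed by the analytic
#' signal (FFT Hilbert transform). Phase convention: 0 deg at the positive
#' peak of an in-band cosine, 180 deg at its trough; reported in degrees in
#' [0, 360).
#'
#' @param x numeric signal (uV).
#' @param fs sampling rate Hz.
#' @param band c(low, high) in Hz; default 0.5-2 Hz (slow-wave validation
#'   band).
#' @param order Butterworth order per pass (total effective order is twice
#'   this because of the forward-backward pass).
#' @return object of class `phase_series`: list with `phase` (degrees per
#'   sample), `envelope` (uV), `band`, `sampling_rate`.
#' @export
instantaneous_phase <- function(x, fs, band = c(0.5, 2), order = 2) {
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie inside (0, Nyquist)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  rms_in <- sqrt(mean(x^2)); rms_out <- sqrt(mean(y^2))
  if (rms_in > 0 && rms_out / rms_in < 0.1)
    warning("little in-band energy: filtered RMS is <10% of input RMS")
  a <- analytic_signal(y)
  structure(list(phase = (Arg(a) * 180 / pi) %% 360,
                 envelope = Mod(a), band = band, sampling_rate = fs),
            class = "phase_series")
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(y) {
  n <- length(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(y) * h, inverse = TRUE) / n
}

#' Phase at event onsets
#'
#' @param ps a [instantaneous_phase()] result.
#' @param onsets event times in seconds.
#' @return numeric vector of angles (degrees in [0, 360)) at the nearest
#'   sample to each onset.
#' @export
phase_at_events <- function(ps, onsets) {
  stopifnot(inherits(ps, "phase_series"))
  n <- length(ps$phase)
  idx <- round(onsets * ps$sampling_rate) + 1L
  bad <- which(idx < 1 | idx > n)
  if (length(bad))
    stop("onset out of range at index ", bad[1])
  ps$phase[idx]
}

#' Circular summary statistics
#'
#' Circular mean (angle of the mean resultant vector), mean resultant
#' length R, and circular SD = sqrt(-2 log R) in radians (so R = 1 implies
#' SD = 0). The mean is flagged undefined when R falls below `r_floor`.
#'
#' @param angles angles in degrees.
#' @param r_floor concentration floor below which the mean direction is
#'   reported but flagged undefined.
#' @return object of class `circular_summary`: list with `mean` (degrees in
#'   [0, 360)), `R`, `sd` (radians), `n`, `mean_defined`.
#' @export
circular_summary <- function(angles, r_floor = 0.05) {
  if (length(angles) < 1) stop("need at least one angle")
  th <- angles * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R > 1 - 1e-12) R <- 1  # guard rounding so R = 1 <=> SD = 0
  mu <- (atan2(S, C) * 180 / pi) %% 360
  if (360 - mu < 1e-9) mu <- 0
  structure(list(mean = mu, R = R,
                 sd = sqrt(pmax(-2 * log(pmax(R, .Machine$double.eps)), 0)),
                 n = length(angles), mean_defined = R >= r_floor),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular mean %.2f deg (R = %.3f, SD = %.3f rad, n = %d)%s\n",
              x$mean, x$R, x$sd, x$n,
              if (x$mean_defined) "" else " [mean undefined: R below floor]"))
  invisible(x)
}

# shortest signed angular difference a - b in degrees, in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Fisher's approximation of the inverse of A(kappa) = I1/I0
kappa_from_r <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Test for a common mean direction of two circular samples
#'
#' Watson-Williams one-way test for equality of circular means, valid for
#' reasonably concentrated samples. When the pooled resultant length falls
#' below the concentration floor the function falls back to a permutation
#' test on the absolute angular difference of the two sample means (the
#' fallback is flagged in the output).
#'
#' @param a,b angle samples in degrees (each n >= 5 for the parametric
#'   test).
#' @param r_min concentration floor for the parametric route.
#' @param n_perm permutations for the fallback.
#' @param seed RNG seed for the fallback.
#' @return list with `statistic`, `p`, `method` ("watson-williams" or
#'   "permutation"), `df` (parametric only).
#' @export
circular_difference_test <- function(a, b, r_min = 0.45, n_perm = 2000,
                                     seed = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("degenerate samples")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  res_len <- function(th) {
    th <- th * pi / 180
    sqrt(sum(cos(th))^2 + sum(sin(th))^2)
  }
  R1 <- res_len(a); R2 <- res_len(b); Rt <- res_len(c(a, b))
  rw <- (R1 + R2) / N
  if (rw >= r_min && n1 >= 5 && n2 >= 5) {
    kappa <- kappa_from_r(rw)
    K <- 1 + 3 / (8 * kappa)
    Fstat <- K * (N - 2) * (R1 + R2 - Rt) / (N - R1 - R2)
    if (!is.finite(Fstat) || Fstat < 0) Fstat <- 0
    p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
    return(list(statistic = Fstat, p = p, method = "watson-williams",
                df = c(1, N - 2)))
  }
  # permutation fallback on |circular mean difference|
  if (!is.null(seed)) set.seed(seed)
  cmean <- function(th) circular_summary(th)$mean
  obs <- abs(ang_diff(cmean(a), cmean(b)))
  pool <- c(a, b)
  null <- replicate(n_perm, {
    idx <- sample.int(N, n1)
    abs(ang_diff(cmean(pool[idx]), cmean(pool[-idx])))
  })
  list(statistic = obs, p = (1 + sum(null >= obs)) / (n_perm + 1),
       method = "permutation", df = NULL)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used for simulation-based tests of the
#' circular machinery.
#'
#' @param n sample size.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in degrees in [0, 360).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_r <- mu * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- mu_r + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out * 180 / pi) %% 360
}
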