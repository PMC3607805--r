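# Spectral analysis: multitaper power spectra with Slepian (DPSS) tapers,
# zero-phase Butterworth band-pass filtering, analytic-signal instantaneous
# phase, and band-limited peak detection.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' commuting matrix.  Tapers are normalised to unit energy and signed so
#' that each has a non-negative mean (even orders) or a non-negative first
#' lobe (odd orders).  Results are cached per `(n, nw, k)`.
#'
#' @param n Taper length (samples).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers; must satisfy `k <= 2 nw - 1`.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  stopifnot(n > 4, nw > 0, k >= 1, k <= 2 * nw - 1)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.eig_cache[[key]])) return(.eig_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(i + 1, i + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1) {            # even order: positive mean
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {                      # odd order: start positive
      s <- which(abs(tap[, j]) > 1e-7)[1]
      if (tap[s, j] < 0) tap[, j] <- -tap[, j]
    }
  }
  .eig_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density
#'
#' Estimates the PSD of one or more trials by the multitaper method: the
#' signal is cut into sliding windows, each window is demeaned, multiplied
#' by `n_tapers` orthogonal Slepian tapers, zero-padded to `pad` samples and
#' Fourier transformed; power is averaged over tapers, windows and finally
#' trials (arithmetic mean in fixed trial order).  With the defaults
#' (500 ms windows at 1 kHz, NW = 3) the spectral resolution half-bandwidth
#' is `NW / T = 6` Hz.
#'
#' @param x Numeric vector (one trial), a list of vectors, a matrix with
#'   one trial per column, or an `ei_lfp` / `ei_rate` object (or list of
#'   them).
#' @param fs Sampling rate (Hz); taken from the object when available.
#' @param window_ms Window length (ms).
#' @param overlap_ms Overlap between consecutive windows (ms).
#' @param nw Time-bandwidth product.
#' @param n_tapers Number of Slepian tapers (default 5 = 2 NW - 1).
#' @param pad FFT length (samples); at least the window length.
#' @return Object of class `ei_psd`: list with `freq` (Hz), `power`
#'   (signal^2 s, one-sided), `per_trial` (matrix, one column per trial),
#'   `half_bandwidth_hz`, `fs`, `n_trials`.
#' @export
multitaper_psd <- function(x, fs = NULL, window_ms = 500, overlap_ms = 50,
                           nw = 3, n_tapers = 5, pad = 512) {
  trials <- .as_trial_list(x)
  if (is.null(fs)) fs <- attr(trials, "fs")
  if (is.null(fs)) stop("`fs` is required for plain numeric input")
  nwin <- round(window_ms * fs / 1000)
  if (any(vapply(trials, length, 1L) < nwin))
    stop("trace shorter than one analysis window")
  pad <- max(pad, nwin)
  hop <- nwin - round(overlap_ms * fs / 1000)
  stopifnot(hop >= 1)
  tap <- dpss_tapers(nwin, nw, n_tapers)
  nf <- floor(pad / 2) + 1
  per_trial <- vapply(trials, function(tr) {
    starts <- seq(1, length(tr) - nwin + 1, by = hop)
    acc <- numeric(nf)
    for (s0 in starts) {
      seg <- tr[s0:(s0 + nwin - 1)]
      seg <- seg - mean(seg)
      for (j in seq_len(n_tapers)) {
        xt <- c(seg * tap[, j], numeric(pad - nwin))
        X <- fft(xt)[seq_len(nf)]
        acc <- acc + (Mod(X)^2) / fs
      }
    }
    acc <- acc / (length(starts) * n_tapers)
    # one-sided scaling
    acc[2:(nf - 1)] <- 2 * acc[2:(nf - 1)]
    if (pad %% 2 == 1) acc[nf] <- 2 * acc[nf]
    acc
  }, numeric(nf))
  power <- rowMeans(per_trial)
  structure(list(freq = (seq_len(nf) - 1) * fs / pad,
                 power = power, per_trial = per_trial,
                 half_bandwidth_hz = nw / (nwin / fs),
                 fs = fs, n_trials = length(trials),
                 window_ms = window_ms, overlap_ms = overlap_ms,
                 nw = nw, n_tapers = n_tapers, pad = pad),
            class = "ei_psd")
}

.as_trial_list <- function(x) {
  fs <- NULL
  pick <- function(obj) {
    if (inherits(obj, "ei_lfp")) { fs <<- obj$fs; obj$lfp }
    else if (inherits(obj, "ei_rate")) { fs <<- obj$fs; obj$rate }
    else if (is.numeric(obj)) as.numeric(obj)
    else stop("unsupported trace type: ", class(obj)[1])
  }
  out <- if (is.matrix(x)) lapply(seq_len(ncol(x)), function(j) x[, j])
    else if (is.list(x) && !inherits(x, c("ei_lfp", "ei_rate")))
      lapply(x, pick)
    else list(pick(x))
  attr(out, "fs") <- fs
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass around `center +/- half_width`, applied
#' forward and backward (`signal::filtfilt`) by default so the filter does
#' not shift spike-phase relations.  A single forward pass
#' (`zero_phase = FALSE`) is available for strict replication of one-pass
#' filtering, at the cost of the filter's group delay.
#'
#' @param x Numeric trace or `ei_lfp` object.
#' @param fs Sampling rate (Hz); taken from the object when available.
#' @param center,half_width Band centre and half-width (Hz); defaults
#'   46.88 +/- 5 Hz, the gamma peak band.
#' @param order Filter order.
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return Filtered numeric vector (an `ei_lfp` input keeps its class).
#' @export
bandpass <- function(x, fs = NULL, center = 46.88, half_width = 5,
                     order = 4, zero_phase = TRUE) {
  is_lfp <- inherits(x, "ei_lfp")
  if (is_lfp) { fs <- x$fs; tr <- x$lfp } else tr <- as.numeric(x)
  if (is.null(fs)) stop("`fs` is required")
  lo <- center - half_width; hi <- center + half_width
  if (lo <= 0 || hi >= fs / 2) stop("band must lie inside (0, Nyquist)")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  y <- if (zero_phase) signal::filtfilt(bf, tr)
       else as.numeric(signal::filter(bf, tr))
  if (is_lfp) { x$lfp <- y; x$band <- c(lo, hi); x } else y
}

#' Instantaneous phase via the analytic signal
#'
#' Hilbert phase of a band-limited trace: the angle of the analytic signal
#' mapped to `[0, 2 pi)`, so local maxima of the trace sit at phase 0 and
#' troughs at phase pi.
#'
#' @param x Filtered numeric trace or `ei_lfp` object.
#' @param fs Sampling rate (Hz); taken from the object when available.
#' @return Object of class `phase_trace`: list with `time` (ms; sample
#'   index based when `fs` only is known), `phase` in `[0, 2 pi)`, `fs`.
#' @export
hilbert_phase <- function(x, fs = NULL) {
  if (inherits(x, "ei_lfp")) {
    tr <- x$lfp; fs <- x$fs; tm <- x$time
  } else {
    tr <- as.numeric(x)
    if (is.null(fs)) stop("`fs` is required")
    tm <- (seq_along(tr) - 0.5) * 1000 / fs
  }
  n <- length(tr)
  X <- fft(tr - mean(tr))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  structure(list(time = tm, phase = Arg(z) %% (2 * pi), fs = fs),
            class = "phase_trace")
}

#' Spectral peak within a band
#'
#' Arg-max of the PSD within `band`, with a flag telling whether that
#' maximum is a genuine line: the candidate must be a local maximum and its
#' log-power must exceed a robust power-law (1/f-type) trend, fitted to the
#' out-of-band part of `fit_range`, by more than `z_thresh` robust standard
#' deviations of the out-of-band residuals.
#'
#' @param psd An `ei_psd` object.
#' @param band Search band (Hz), default the gamma band 30-90 Hz.
#' @param fit_range Frequencies used to fit the background trend (Hz).
#' @param z_thresh Detection threshold in robust SD units.
#' @return List with `freq` (Hz), `power`, `has_peak` (logical), `z`.
#' @export
spectral_peak <- function(psd, band = c(30, 90), fit_range = c(8, 200),
                          z_thresh = 4) {
  f <- psd$freq; p <- psd$power
  inb <- which(f >= band[1] & f <= band[2])
  if (length(inb) < 3) stop("band contains too few frequency bins")
  imax <- inb[which.max(p[inb])]
  # robust log-log background fit, excluding the search band
  fit_idx <- which(f >= fit_range[1] & f <= fit_range[2] &
                     (f < band[1] | f > band[2]) & p > 0)
  lx <- log10(f[fit_idx]); ly <- log10(p[fit_idx])
  fit <- MASS::rlm(ly ~ lx, maxit = 50)
  res <- ly - stats::fitted(fit)
  s <- stats::mad(res)
  pred_pk <- sum(stats::coef(fit) * c(1, log10(f[imax])))
  z <- (log10(p[imax]) - pred_pk) / s
  local_max <- imax > 1 && imax < length(p) &&
    p[imax] >= p[imax - 1] && p[imax] >= p[imax + 1] &&
    imax != inb[1] && imax != inb[length(inb)]
  list(freq = f[imax], power = p[imax],
       has_peak = isTRUE(local_max && z > z_thresh), z = z)
}

#' Write a power spectrum as annotated CSV
#'
#' Columns `freq_hz,power`, preceded by `#` comment lines echoing the
#' estimator configuration.
#' @param psd An `ei_psd` object.
#' @param path Output file.
#' @export
write_psd_csv <- function(psd, path) {
  comments <- sprintf(
    "multitaper: window %g ms, overlap %g ms, NW %g, K %d, pad %d, trials %d",
    psd$window_ms, psd$overlap_ms, psd$nw, psd$n_tapers, psd$pad,
    psd$n_trials)
  write_curve_csv(data.frame(freq_hz = psd$freq, power = psd$power),
                  path, comments)
}
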