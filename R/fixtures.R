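# Synthetic fixture generators.  Each generator emulates the statistical
# structure one of the analysis stages assumes and returns its own ground
# truth alongside the data, so the analyses can be tested for recovery
# without running the full network.

#' Toy LFP: a spectral line on a 1/f^2 background
#'
#' Generates `duration` ms of signal at `fs` Hz: a cosine at `freq` Hz on
#' top of Gaussian noise shaped to a 1/f^2 power spectrum in the frequency
#' domain.  `snr` is the ratio of line variance to background variance
#' (`0` gives pure noise, `Inf` a pure cosine).
#'
#' @param freq Line frequency (Hz), below Nyquist.
#' @param snr Line-to-background variance ratio.
#' @param duration Length (ms).
#' @param fs Sampling rate (Hz).
#' @param seed Optional seed.
#' @return List with `time` (ms), `lfp`, `fs`, and `truth` (`freq`,
#'   `trough_times_ms` of the pure line, `snr`).
#' @export
make_toy_lfp <- function(freq = 45, snr = 10, duration = 3000, fs = 1000,
                         seed = NULL) {
  stopifnot(freq < fs / 2, duration > 0, snr >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs / 1000)
  tt <- (seq_len(n) - 0.5) / fs          # seconds
  if (is.infinite(snr)) {
    bg <- numeric(n); amp <- 1
  } else {
    w <- rnorm(n)
    W <- fft(w)
    f <- c(0, seq_len(n - 1)) * fs / n
    f <- pmin(f, fs - f)                  # two-sided frequency magnitude
    shape <- ifelse(f > 0, 1 / f, 0)      # amplitude ~ 1/f -> power ~ 1/f^2
    bg <- Re(fft(W * shape, inverse = TRUE) / n)
    bg <- (bg - mean(bg)) / sd(bg)
    amp <- sqrt(2 * snr)                  # cosine variance = amp^2 / 2
  }
  x <- amp * cos(2 * pi * freq * tt) + if (is.infinite(snr)) 0 else bg
  troughs <- 1000 * (seq(0.5, by = 1, length.out = floor(freq * duration / 1000)) / freq)
  list(time = tt * 1000, lfp = x, fs = fs,
       truth = list(freq = freq, snr = snr,
                    trough_times_ms = troughs[troughs < duration]))
}

#' Phase-locked Poisson spike train
#'
#' Inhomogeneous Poisson spikes whose intensity follows a von-Mises-type
#' modulation of a reference oscillation,
#' \eqn{\lambda(t) = \bar r\, e^{\kappa \cos(\phi(t) - \phi_0)} /
#' I_0(\kappa)}, where \eqn{\phi(t) = 2\pi f t} is the exact oscillation
#' phase (returned alongside as the reference phase trace) and the
#' \eqn{I_0} normalisation keeps the time-averaged rate at `rate`.
#'
#' @param rate Mean firing rate (spikes/s), > 0.
#' @param kappa Locking concentration (>= 0; 0 gives a homogeneous train).
#' @param preferred Preferred phase (radians).
#' @param freq Oscillation frequency (Hz).
#' @param duration Length (ms).
#' @param n_neurons Number of independent trains.
#' @param fs Thinning grid rate (Hz).
#' @param seed Optional seed.
#' @return List with `raster` (`neuron`, `time_ms`), `phase`
#'   (a `phase_trace`), and `truth` (`kappa`, `preferred`, `freq`, `rate`).
#' @export
make_locked_spiketrain <- function(rate = 20, kappa = 2, preferred = pi,
                                   freq = 45, duration = 10000,
                                   n_neurons = 1, fs = 1000, seed = NULL) {
  stopifnot(rate > 0, kappa >= 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs / 1000)
  tt <- (seq_len(n) - 0.5) / fs
  phi <- (2 * pi * freq * tt) %% (2 * pi)
  lam <- rate * exp(kappa * cos(phi - preferred)) / besselI(kappa, 0)
  p <- lam / fs
  if (max(p) > 0.2)
    warning("lambda/fs exceeds 0.2; increase fs for faithful thinning")
  rasters <- lapply(seq_len(n_neurons), function(i) {
    hit <- which(runif(n) < p)
    data.frame(neuron = rep(i, length(hit)), time_ms = tt[hit] * 1000)
  })
  list(raster = do.call(rbind, rasters),
       phase = structure(list(time = tt * 1000, phase = phi, fs = fs),
                         class = "phase_trace"),
       truth = list(kappa = kappa, preferred = preferred, freq = freq,
                    rate = rate))
}

#' Spike train with a bimodal ISI mixture
#'
#' Draws interspike intervals i.i.d. from a two-component lognormal mixture
#' whose components are centred (as medians) on `1000/slow_rate` and
#' `1000/fast_rate` ms.  On the rate axis (1/ISI) the density is again a
#' two-component lognormal mixture; its closed form is minimised
#' numerically between the modes and returned as ground truth, together
#' with the slow-side mass below that minimum.
#'
#' @param slow_rate,fast_rate Mode rates (spikes/s); must differ by at
#'   least a factor of 2.
#' @param weight_slow Mixture weight of the slow component, in `[0, 1]`.
#' @param sdlog Log-scale spread of each component.
#' @param n_isi Number of intervals to draw.
#' @param seed Optional seed.
#' @return List with `spike_times_ms` (cumulated train), `isis_ms`,
#'   `rates_hz`, and `truth` (`min_rate_hz`, the analytic inter-mode
#'   density minimum; `slow_fraction`, the mixture mass below it;
#'   `unimodal` flag; `density(r)`, the closed-form rate density).
#' @export
make_bimodal_isi_train <- function(slow_rate = 30, fast_rate = 120,
                                   weight_slow = 0.64, sdlog = 0.3,
                                   n_isi = 10000, seed = NULL) {
  stopifnot(fast_rate >= 2 * slow_rate, weight_slow >= 0, weight_slow <= 1,
            sdlog > 0, n_isi > 0)
  if (!is.null(seed)) set.seed(seed)
  comp <- runif(n_isi) < weight_slow
  rates <- ifelse(comp,
                  rlnorm(n_isi, log(slow_rate), sdlog),
                  rlnorm(n_isi, log(fast_rate), sdlog))
  isis <- 1000 / rates
  dens <- function(r)
    weight_slow * stats::dlnorm(r, log(slow_rate), sdlog) +
      (1 - weight_slow) * stats::dlnorm(r, log(fast_rate), sdlog)
  unimodal <- weight_slow %in% c(0, 1)
  if (unimodal) {
    min_rate <- NA_real_; slow_frac <- NA_real_
  } else {
    min_rate <- optimize(dens, c(slow_rate, fast_rate))$minimum
    slow_frac <- weight_slow * stats::plnorm(min_rate, log(slow_rate), sdlog) +
      (1 - weight_slow) * stats::plnorm(min_rate, log(fast_rate), sdlog)
  }
  list(spike_times_ms = cumsum(isis), isis_ms = isis, rates_hz = rates,
       truth = list(min_rate_hz = min_rate, slow_fraction = slow_frac,
                    unimodal = unimodal, density = dens,
                    slow_rate = slow_rate, fast_rate = fast_rate,
                    weight_slow = weight_slow))
}
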