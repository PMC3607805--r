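# Network model: random connectivity with gamma-distributed delays,
# double-exponential synaptic conductances, Ornstein-Uhlenbeck-modulated
# external Poisson drive, and the Heun time-stepping loop.

#' Synaptic kinetics and strength
#'
#' A single synaptic conductance follows the double exponential
#' \deqn{g_{syn}(t) = \frac{g'_{syn}}{\tau_d - \tau_r}
#'   \left[e^{-(t - t_j)/\tau_d} - e^{-(t - t_j)/\tau_r}\right]}
#' after a presynaptic event at \eqn{t_j}, and the synaptic current is
#' \eqn{-g_{syn}(t)\,(V - E_{syn})} (depolarising for AMPA at rest,
#' hyperpolarising for GABA).  Conductance scales are given in nS and
#' converted to uS internally.
#'
#' @param kind `"AMPA_recurrent"`, `"AMPA_external"` or `"GABA"`.
#' @param tau_r,tau_d Rise and decay times (ms); must satisfy
#'   `tau_d > tau_r > 0`.  Defaults: AMPA 0.5/2 ms, GABA 2/5 ms.
#' @param E_syn Reversal potential (mV). Defaults: AMPA 0, GABA -70.
#' @param g_prime Conductance scale (nS).  Defaults: recurrent AMPA 2.5,
#'   external AMPA 3.2, GABA 240.
#' @return Object of class `synapse_params`.
#' @export
synapse_params <- function(kind = c("AMPA_recurrent", "AMPA_external", "GABA"),
                           tau_r = NULL, tau_d = NULL, E_syn = NULL,
                           g_prime = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA_recurrent = list(tau_r = 0.5, tau_d = 2, E_syn = 0, g_prime = 2.5),
    AMPA_external  = list(tau_r = 0.5, tau_d = 2, E_syn = 0, g_prime = 3.2),
    GABA           = list(tau_r = 2, tau_d = 5, E_syn = -70, g_prime = 240))
  p <- list(kind = kind,
            tau_r = if (is.null(tau_r)) def$tau_r else tau_r,
            tau_d = if (is.null(tau_d)) def$tau_d else tau_d,
            E_syn = if (is.null(E_syn)) def$E_syn else E_syn,
            g_prime = if (is.null(g_prime)) def$g_prime else g_prime)
  stopifnot(p$tau_d > p$tau_r, p$tau_r > 0, p$g_prime >= 0)
  if (kind == "GABA") stopifnot(p$E_syn < -65) else stopifnot(p$E_syn >= 0)
  structure(p, class = "synapse_params")
}

#' Peak time of the double-exponential conductance
#'
#' \eqn{t^* = \frac{\tau_d \tau_r}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)} after
#' the event; 0.924 ms for the AMPA defaults.
#' @param syn A [synapse_params()] object.
#' @export
conductance_peak_time <- function(syn) {
  with(syn, tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r))
}

#' Closed-form conductance time course of synaptic events
#'
#' Evaluates \eqn{g_{syn}(t)} for a superposition of events at
#' `event_times`, in uS (the `g_prime` nS scale is converted).  Linearity
#' holds: simultaneous events add their conductances.
#'
#' @param syn A [synapse_params()] object.
#' @param t Evaluation times (ms).
#' @param event_times Presynaptic event times (ms).
#' @return Conductance (uS) at each `t`.
#' @export
conductance_timecourse <- function(syn, t, event_times = 0) {
  g <- numeric(length(t))
  for (tj in event_times) {
    dtj <- t - tj
    act <- dtj >= 0
    g[act] <- g[act] + syn$g_prime * 1e-3 / (syn$tau_d - syn$tau_r) *
      (exp(-dtj[act] / syn$tau_d) - exp(-dtj[act] / syn$tau_r))
  }
  g
}

#' Synaptic current from a conductance state
#'
#' \eqn{I_{syn} = -g_{syn}(t)\,(V_{post} - E_{syn})} in nA: the sign
#' convention that makes AMPA input depolarising and GABA input
#' hyperpolarising when added to the membrane equation.  At
#' `V_post = E_syn` the current reverses (is zero).
#'
#' @param syn A [synapse_params()] object.
#' @param t Times since the event(s) (ms).
#' @param V_post Postsynaptic potential (mV).
#' @param event_times Presynaptic event times (ms).
#' @return Current (nA) at each `t`.
#' @export
synaptic_current <- function(syn, t, V_post, event_times = 0) {
  -conductance_timecourse(syn, t, event_times) * (V_post - syn$E_syn)
}

#' Axonal delay distribution
#'
#' Recurrent synaptic delays are gamma distributed; the printed mean (2 ms)
#' and variance (4 ms^2) are moment-matched to shape `mean^2/variance` and
#' scale `variance/mean` (shape 1, scale 2 ms under defaults, i.e. an
#' exponential law).  External events carry no delay.
#'
#' @param mean Mean delay (ms).
#' @param variance Delay variance (ms^2).
#' @return Object of class `delay_params` with `shape` and `scale` filled in.
#' @export
delay_params <- function(mean = 2, variance = 4) {
  stopifnot(mean > 0, variance > 0)
  structure(list(mean = mean, variance = variance,
                 shape = mean^2 / variance, scale = variance / mean),
            class = "delay_params")
}

#' External drive parameters
#'
#' Each neuron receives an independent Poisson train of excitatory events
#' whose common instantaneous rate is `mean_rate` plus a stationary
#' Ornstein-Uhlenbeck fluctuation of standard deviation `sigma *
#' sigma_scale` and correlation time `tau_ou`.  The fluctuation spectrum is
#' flat up to the cut-off `1/(2 pi tau_ou)` (9.9 Hz under defaults) and
#' falls as `1/f^2` beyond it.  `sigma_scale` (default 1) is provided
#' because the default `sigma` of 0.6 spikes/s is minute against the mean of
#' 8500 spikes/s; scaling it up makes the external-rate fluctuations visible
#' to downstream rate-coding analyses without reinterpreting the defaults.
#'
#' @param mean_rate Mean event rate per neuron (spikes/s).
#' @param sigma OU standard deviation (spikes/s).
#' @param sigma_scale Dimensionless multiplier applied to `sigma`.
#' @param tau_ou OU correlation time (ms).
#' @return Object of class `drive_params`.
#' @export
drive_params <- function(mean_rate = 8500, sigma = 0.6, sigma_scale = 1,
                         tau_ou = 16) {
  stopifnot(mean_rate >= 0, sigma >= 0, tau_ou > 0)
  structure(list(mean_rate = mean_rate, sigma = sigma,
                 sigma_scale = sigma_scale, tau_ou = tau_ou),
            class = "drive_params")
}

#' Spectral cut-off frequency of the OU drive
#'
#' `1/(2 pi tau_ou)` in Hz (with `tau_ou` in ms).
#' @param drive A [drive_params()] object.
#' @export
ou_cutoff_hz <- function(drive) 1000 / (2 * pi * drive$tau_ou)

#' Full network configuration
#'
#' Bundles all parameters of the default 2000-neuron balanced network:
#' 80% excitatory / 20% inhibitory cells, independent-Bernoulli connectivity
#' with 200 partners on average, gamma-distributed recurrent delays,
#' double-exponential synapses, and the OU-modulated external Poisson drive.
#'
#' @param n Number of neurons.
#' @param frac_exc Excitatory fraction.
#' @param p_connect Connection probability for each ordered pair.
#' @param neurons List with `excitatory` and `inhibitory`
#'   [neuron_params()] presets.
#' @param synapses List with `ampa_recurrent`, `ampa_external`, `gaba`
#'   [synapse_params()] objects.
#' @param delay A [delay_params()] object.
#' @param drive A [drive_params()] object.
#' @param duration Trial length (ms).
#' @param dt Integration step (ms).
#' @param n_record_exc,n_record_inh How many excitatory/inhibitory neurons
#'   get full current and voltage traces (recorded at `record_bin_ms`).
#' @param record_bin_ms Width of the recorded-trace bins (ms).
#' @param v_th,lockout Spike detection threshold (mV) and dead time (ms).
#' @param tau_d_gaba Convenience override for the GABA decay time (ms).
#' @return Object of class `network_config`.
#' @export
network_config <- function(n = 2000, frac_exc = 0.8, p_connect = 0.1,
                           neurons = list(
                             excitatory = neuron_params("excitatory"),
                             inhibitory = neuron_params("inhibitory")),
                           synapses = list(
                             ampa_recurrent = synapse_params("AMPA_recurrent"),
                             ampa_external = synapse_params("AMPA_external"),
                             gaba = synapse_params("GABA")),
                           delay = delay_params(),
                           drive = drive_params(),
                           duration = 3000, dt = 0.05,
                           n_record_exc = 100, n_record_inh = 25,
                           record_bin_ms = 1,
                           v_th = 0, lockout = 2,
                           tau_d_gaba = NULL) {
  if (!is.null(tau_d_gaba))
    synapses$gaba <- synapse_params("GABA", tau_d = tau_d_gaba)
  stopifnot(n >= 2, frac_exc > 0, frac_exc < 1,
            p_connect >= 0, p_connect < 1, dt > 0, duration > dt)
  structure(list(n = n, frac_exc = frac_exc, p_connect = p_connect,
                 neurons = neurons, synapses = synapses,
                 delay = delay, drive = drive,
                 duration = duration, dt = dt,
                 n_record_exc = n_record_exc, n_record_inh = n_record_inh,
                 record_bin_ms = record_bin_ms,
                 v_th = v_th, lockout = lockout),
            class = "network_config")
}

#' Hash of a configuration
#'
#' MD5 digest of the serialised configuration, attached to every simulation
#' result so outputs can be traced to the exact parameter set.
#' @param config Any R object (typically a [network_config()]).
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Random connectivity with gamma-distributed delays
#'
#' Every ordered pair (i, j), i != j, is connected independently with
#' probability `p_connect`; no structure beyond that is imposed.  Each edge
#' gets an i.i.d. gamma-distributed delay.  With `n = 2000` and
#' `p_connect = 0.1` the mean out-degree is 200.
#'
#' @param n Number of neurons.
#' @param frac_exc Excitatory fraction (neurons `1..round(n*frac_exc)` are
#'   excitatory).
#' @param p_connect Connection probability.
#' @param delay A [delay_params()] object.
#' @param seed Optional integer seed.
#' @return Object of class `connectivity_graph`: list with `offsets`
#'   (0-based CSR offsets, length n+1), `targets` (1-based postsynaptic
#'   ids), `delays_ms`, `n`, `n_exc`.
#' @export
build_connectivity <- function(n, frac_exc = 0.8, p_connect = 0.1,
                               delay = delay_params(), seed = NULL) {
  if (n < 2) stop("need at least 2 neurons")
  stopifnot(p_connect >= 0, p_connect < 1)
  if (!is.null(seed)) set.seed(seed)
  n_exc <- round(n * frac_exc)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- which(runif(n) < p_connect)
    targets[[i]] <- tg[tg != i]
  }
  deg <- lengths(targets)
  offsets <- c(0L, cumsum(deg))
  targets <- unlist(targets, use.names = FALSE)
  if (is.null(targets)) targets <- integer(0)
  delays <- rgamma(length(targets), shape = delay$shape, scale = delay$scale)
  structure(list(offsets = as.integer(offsets),
                 targets = as.integer(targets),
                 delays_ms = delays, n = n, n_exc = n_exc),
            class = "connectivity_graph")
}

#' Ornstein-Uhlenbeck rate path
#'
#' Generates the instantaneous rate of the external drive,
#' `mean_rate + x(t)`, where `x` solves
#' \deqn{dx = -x/\tau\, dt + \sigma\sqrt{2\tau}/\tau\, dW}
#' (stationary standard deviation `sigma`).  Integrated with the stochastic
#' Heun scheme, using the same Wiener increment in predictor and corrector;
#' for this linear additive-noise equation that is the exact recursion
#' \eqn{x_{k+1} = a x_k + b\,\Delta W_k} with
#' \eqn{a = 1 - dt/\tau + (dt/\tau)^2/2}.  Negative total rates are clipped
#' to zero.
#'
#' @param drive A [drive_params()] object.
#' @param duration Path length (ms).
#' @param dt Time step (ms); must satisfy `dt <= tau_ou/10`.
#' @param x0 Initial fluctuation; `NULL` draws from the stationary law.
#' @return List with `time` (ms) and `lambda` (spikes/s), length
#'   `duration/dt + 1`.
#' @export
ou_rate_path <- function(drive, duration, dt = 0.05, x0 = NULL) {
  stopifnot(dt <= drive$tau_ou / 10)
  n_steps <- round(duration / dt)
  s <- drive$sigma * drive$sigma_scale
  if (s == 0) {
    lam <- rep(drive$mean_rate, n_steps + 1)
    return(list(time = seq(0, by = dt, length.out = n_steps + 1),
                lambda = lam))
  }
  r <- dt / drive$tau_ou
  a <- 1 - r + r^2 / 2
  gain <- s * sqrt(2 * drive$tau_ou) / drive$tau_ou * (1 - r / 2)
  dW <- rnorm(n_steps, sd = sqrt(dt))
  if (is.null(x0)) x0 <- rnorm(1, sd = s)
  x <- stats::filter(gain * dW, a, method = "recursive", init = x0)
  lam <- pmax(0, drive$mean_rate + c(x0, as.numeric(x)))
  list(time = seq(0, by = dt, length.out = n_steps + 1), lambda = lam)
}

#' Poisson event trains from a shared rate path
#'
#' Thins each time bin independently per neuron with probability
#' `lambda(t) * dt`, so all neurons share the rate path but have independent
#' event times.  Warns when `lambda * dt` exceeds 0.2 anywhere, where the
#' one-event-per-bin approximation degrades (the network simulator itself
#' draws per-bin Poisson counts instead and has no such restriction).
#'
#' @param lambda Rate path (spikes/s), sampled every `dt` ms.
#' @param dt Bin width (ms).
#' @param n_neurons Number of independent trains.
#' @return List of event-time vectors (ms).
#' @export
external_spike_trains <- function(lambda, dt, n_neurons) {
  stopifnot(all(lambda >= 0))
  p <- lambda * 1e-3 * dt
  if (max(p) > 0.2)
    warning("lambda * dt exceeds 0.2: thin-bin Bernoulli approximation ",
            "degrades; reduce dt")
  tgrid <- (seq_along(lambda) - 1) * dt
  lapply(seq_len(n_neurons), function(i) tgrid[runif(length(p)) < p])
}

#' Peak postsynaptic potential of a single event
#'
#' Places a postsynaptic neuron at its resting state, delivers one
#' conductance event, and returns the peak absolute voltage deflection.
#' Used to verify that the default conductance scales keep PSPs in the
#' physiological range.
#'
#' @param post_params [neuron_params()] of the postsynaptic cell.
#' @param syn A [synapse_params()] object.
#' @param dt Integration step (ms).
#' @return Peak deflection magnitude (mV).
#' @export
psp_amplitude <- function(post_params, syn, dt = 0.05) {
  if (syn$g_prime == 0) return(0)
  # settle to rest (the fixed point is within a whisker of V_L)
  rest <- simulate_single(post_params, I_const = 0, duration = 500, dt = dt,
                          record = FALSE)
  V_rest <- rest$V_end
  sim <- simulate_single(post_params, I_const = 0, duration = 150, dt = dt,
                         V0 = V_rest, n0 = rest$n_end, h0 = rest$h_end,
                         syn = list(times = 20, g_prime = syn$g_prime * 1e-3,
                                    tau_r = syn$tau_r, tau_d = syn$tau_d,
                                    E_syn = syn$E_syn))
  max(abs(sim$V - V_rest))
}

#' Run a full network trial
#'
#' Builds the connectivity, draws the OU rate path and per-neuron initial
#' conditions, and integrates all neurons with the Heun scheme.  Recurrent
#' spikes are delivered after their edge delay (snapped to the integration
#' grid); external events are applied with zero delay.  Initial potentials
#' are jittered uniformly in `[V_L - 5, V_L]` mV with gating at steady
#' state, so connectivity, initial conditions and noise all change from
#' trial to trial with the seed.  The run is bitwise reproducible for a
#' given seed.
#'
#' @param config A [network_config()] object.
#' @param seed Integer seed for the trial.
#' @param graph Optional pre-built [build_connectivity()] graph (otherwise
#'   drawn from the seed).
#' @return Object of class `ei_sim`: list with
#'   \describe{
#'     \item{raster}{data.frame `neuron`, `time_ms`, `population`}
#'     \item{lfp_ampa, lfp_gaba}{population means over excitatory cells of
#'       |I_AMPA| and |I_GABA| (nA) on the integration grid}
#'     \item{mean_ext, mean_net}{population-mean external and net synaptic
#'       current onto excitatory cells (nA), integration grid}
#'     \item{lambda}{realised external rate path (spikes/s), integration grid}
#'     \item{traces}{list of matrices `V`, `I_ampa`, `I_gaba`, `I_syn`
#'       (recorded neurons x `record_bin_ms` bins)}
#'     \item{record_ids}{neuron ids of the recorded subset}
#'     \item{config, config_hash, seed, dt, duration}{provenance}
#'   }
#' @export
run_simulation <- function(config = network_config(), seed = 1,
                           graph = NULL) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  n <- config$n
  n_exc <- round(n * config$frac_exc)
  if (is.null(graph))
    graph <- build_connectivity(n, config$frac_exc, config$p_connect,
                                config$delay)
  stopifnot(graph$n == n)
  dt <- config$dt
  n_steps <- round(config$duration / dt)

  ou <- ou_rate_path(config$drive, config$duration, dt)

  exc <- config$neurons$excitatory
  inh <- config$neurons$inhibitory
  Cm <- c(rep(exc$C_m, n_exc), rep(inh$C_m, n - n_exc))
  V0 <- exc$V_L - runif(n, 0, 5)

  syn_a <- config$synapses$ampa_recurrent
  syn_e <- config$synapses$ampa_external
  syn_g <- config$synapses$gaba
  stopifnot(syn_a$tau_r == syn_e$tau_r, syn_a$tau_d == syn_e$tau_d,
            syn_a$E_syn == syn_e$E_syn)

  rec_ids <- c(seq_len(min(config$n_record_exc, n_exc)),
               n_exc + seq_len(min(config$n_record_inh, n - n_exc)))
  rec_stride <- round(config$record_bin_ms / dt)

  res <- cpp_run_network(
    n, n_exc,
    graph$offsets, graph$targets - 1L,
    as.integer(round(graph$delays_ms / dt)),
    ou$lambda,
    Cm, .np_shared(exc),
    syn_a$tau_r, syn_a$tau_d, syn_a$E_syn,
    syn_a$g_prime * 1e-3, syn_e$g_prime * 1e-3,
    syn_g$tau_r, syn_g$tau_d, syn_g$E_syn,
    syn_g$g_prime * 1e-3,
    dt, n_steps, V0,
    as.integer(rec_ids - 1L), rec_stride,
    config$v_th, config$lockout)

  population <- factor(ifelse(res$spike_id <= n_exc,
                              "excitatory", "inhibitory"),
                       levels = c("excitatory", "inhibitory"))
  raster <- data.frame(neuron = res$spike_id, time_ms = res$spike_t,
                       population = population)
  raster <- raster[order(raster$neuron, raster$time_ms), , drop = FALSE]
  rownames(raster) <- NULL

  traces <- list(V = res$rec_V, I_ampa = res$rec_ampa,
                 I_gaba = res$rec_gaba, I_syn = res$rec_syn)
  for (nm in names(traces)) rownames(traces[[nm]]) <- rec_ids

  structure(list(raster = raster,
                 lfp_ampa = res$lfp_ampa, lfp_gaba = res$lfp_gaba,
                 mean_ext = res$mean_ext, mean_net = res$mean_net,
                 lambda = ou$lambda,
                 traces = traces, record_ids = rec_ids,
                 trace_bin_ms = config$record_bin_ms,
                 n = n, n_exc = n_exc,
                 dt = dt, duration = config$duration,
                 config = config, config_hash = config_hash(config),
                 seed = seed),
            class = "ei_sim")
}

#' @export
print.ei_sim <- function(x, ...) {
  re <- with(x$raster, sum(population == "excitatory")) /
    (x$n_exc * x$duration / 1000)
  ri <- with(x$raster, sum(population == "inhibitory")) /
    ((x$n - x$n_exc) * x$duration / 1000)
  cat(sprintf(
    "<ei_sim> %d neurons (%d exc), %g ms, %d spikes (E %.1f Hz, I %.1f Hz), seed %s\n",
    x$n, x$n_exc, x$duration, nrow(x$raster), re, ri, format(x$seed)))
  invisible(x)
}

#' Write a spike raster as CSV
#'
#' Columns `neuron_id,time_ms,population`.
#' @param sim An `ei_sim` object (or a raster data.frame).
#' @param path Output file.
#' @export
write_raster_csv <- function(sim, path) {
  r <- if (inherits(sim, "ei_sim")) sim$raster else sim
  out <- data.frame(neuron_id = r$neuron, time_ms = r$time_ms,
                    population = as.character(r$population))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
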