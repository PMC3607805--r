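# Population-level observables derived from a simulation: LFP proxy,
# time-resolved population firing rate, interspike intervals and
# instantaneous rates, and the network-embedded f-I scatter.

#' LFP proxy from synaptic currents
#'
#' The local field potential is modelled as the population average, over the
#' excitatory cells, of the absolute synaptic currents,
#' \deqn{LFP = R_e \langle |I_{AMPA}| + |I_{GABA}| \rangle,}
#' with \eqn{R_e} the electrode resistance (1 Mohm by default), so nA times
#' Mohm gives mV.  `I_AMPA` includes both the external-train and the
#' recurrent excitatory currents.  The average is taken per neuron on the
#' integration grid inside the simulator (absolute value first, then
#' population mean), and is downsampled here by averaging to `bin_ms` bins
#' so that a 500 ms analysis window holds 500 samples at the default 1 ms
#' bin.
#'
#' @param sim An `ei_sim` object from [run_simulation()].
#' @param R_e Electrode resistance (Mohm).
#' @param bin_ms Output sampling bin (ms).
#' @return Object of class `ei_lfp`: list with `time` (bin centres, ms),
#'   `lfp` (mV), `fs` (Hz), `R_e`.
#' @export
compute_lfp <- function(sim, R_e = 1, bin_ms = 1) {
  if (is.null(sim$lfp_ampa) || is.null(sim$lfp_gaba))
    stop("simulation result carries no recorded synaptic currents")
  raw <- R_e * (sim$lfp_ampa + sim$lfp_gaba)
  lfp <- bin_average(raw[-1], sim$dt, bin_ms)
  structure(list(time = (seq_along(lfp) - 0.5) * bin_ms,
                 lfp = lfp, fs = 1000 / bin_ms, R_e = R_e),
            class = "ei_lfp")
}

#' Average a dt-grid signal into coarser bins
#'
#' @param x Signal sampled every `dt` ms (first sample at t = dt).
#' @param dt Input step (ms).
#' @param bin_ms Output bin (ms); must be a multiple of `dt`.
#' @return Vector of bin means.
#' @export
bin_average <- function(x, dt, bin_ms) {
  k <- round(bin_ms / dt)
  nb <- floor(length(x) / k)
  colMeans(matrix(x[seq_len(nb * k)], nrow = k))
}

#' Time-resolved population firing rate
#'
#' Histogram of spike times with `bin_ms` bins, normalised to spikes per
#' second per neuron, so `sum(rate) * bin * N` recovers the spike count.
#'
#' @param sim An `ei_sim` object, or a raster data.frame with `time_ms`
#'   (then `n_neurons` and `duration` are required).
#' @param bin_ms Bin width (ms).
#' @param population `"excitatory"`, `"inhibitory"` or `"all"`.
#' @param n_neurons,duration Needed when `sim` is a bare raster.
#' @return Object of class `ei_rate`: list with `time` (bin centres, ms),
#'   `rate` (spikes/s per neuron), `bin_ms`, `n_neurons`, `fs`.
#' @export
population_rate <- function(sim, bin_ms = 1,
                            population = c("all", "excitatory", "inhibitory"),
                            n_neurons = NULL, duration = NULL) {
  population <- match.arg(population)
  if (inherits(sim, "ei_sim")) {
    raster <- sim$raster
    duration <- sim$duration
    n_neurons <- switch(population, all = sim$n, excitatory = sim$n_exc,
                        inhibitory = sim$n - sim$n_exc)
  } else {
    raster <- sim
    if (is.null(n_neurons) || is.null(duration))
      stop("`n_neurons` and `duration` are required for a bare raster")
  }
  stopifnot(bin_ms > 0)
  if (population != "all" && "population" %in% names(raster))
    raster <- raster[raster$population == population, , drop = FALSE]
  edges <- seq(0, duration, by = bin_ms)
  counts <- if (nrow(raster) == 0) rep(0, length(edges) - 1) else
    as.numeric(table(cut(raster$time_ms, edges, include.lowest = TRUE)))
  rate <- counts / n_neurons / (bin_ms / 1000)
  structure(list(time = edges[-1] - bin_ms / 2, rate = rate,
                 bin_ms = bin_ms, n_neurons = n_neurons,
                 fs = 1000 / bin_ms, population = population),
            class = "ei_rate")
}

#' Interspike intervals and instantaneous rates
#'
#' One row per consecutive spike pair of each neuron; the instantaneous
#' rate is the reciprocal interval, in spikes/s.
#'
#' @param sim An `ei_sim` object or a raster data.frame with `neuron`,
#'   `time_ms` and optionally `population`.
#' @param population Restrict to one population (default: keep all).
#' @return data.frame with `neuron`, `population`, `t_start`, `t_end`,
#'   `isi_ms`, `rate_hz`.
#' @export
instantaneous_rates <- function(sim,
                                population = c("all", "excitatory",
                                               "inhibitory")) {
  population <- match.arg(population)
  raster <- if (inherits(sim, "ei_sim")) sim$raster else sim
  if (population != "all" && "population" %in% names(raster))
    raster <- raster[raster$population == population, , drop = FALSE]
  if (nrow(raster) == 0)
    return(data.frame(neuron = integer(0), population = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      isi_ms = numeric(0), rate_hz = numeric(0)))
  raster <- raster[order(raster$neuron, raster$time_ms), , drop = FALSE]
  same <- duplicated(raster$neuron)
  # rows 2..k of each neuron's block close an ISI
  idx <- which(same)
  if (length(idx) == 0)
    return(data.frame(neuron = integer(0), population = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      isi_ms = numeric(0), rate_hz = numeric(0)))
  isi <- raster$time_ms[idx] - raster$time_ms[idx - 1]
  pop <- if ("population" %in% names(raster))
    as.character(raster$population[idx]) else NA_character_
  data.frame(neuron = raster$neuron[idx], population = pop,
             t_start = raster$time_ms[idx - 1], t_end = raster$time_ms[idx],
             isi_ms = isi, rate_hz = 1000 / isi)
}

#' Network-embedded f-I scatter
#'
#' For every interspike interval of every recorded neuron, pairs the
#' instantaneous rate (1/ISI) with the net synaptic current averaged over
#' that interval.  The average is taken on the open interval between the
#' two spikes, excluding 1 ms on each side so the spike-current artefacts
#' do not bias the mean; intervals too short to contain a clean sample are
#' dropped.
#'
#' @param sim An `ei_sim` object with recorded traces.
#' @return data.frame with `neuron`, `population`, `isi_ms`, `rate_hz`,
#'   `mean_current_na`.
#' @export
embedded_fi_scatter <- function(sim) {
  if (is.null(sim$traces$I_syn) || nrow(sim$traces$I_syn) == 0)
    stop("no recorded neurons: set n_record_exc/n_record_inh in the config")
  bin <- sim$trace_bin_ms
  isis <- instantaneous_rates(sim)
  isis <- isis[isis$neuron %in% sim$record_ids, , drop = FALSE]
  if (nrow(isis) == 0)
    stop("recorded neurons produced no interspike intervals")
  tr <- sim$traces$I_syn
  row_of <- match(isis$neuron, sim$record_ids)
  nb <- ncol(tr)
  mean_cur <- vapply(seq_len(nrow(isis)), function(r) {
    lo <- ceiling((isis$t_start[r] + 1) / bin) + 1L
    hi <- floor((isis$t_end[r] - 1) / bin)
    if (hi < lo || hi > nb) return(NA_real_)
    mean(tr[row_of[r], lo:hi])
  }, numeric(1))
  out <- data.frame(neuron = isis$neuron, population = isis$population,
                    isi_ms = isis$isi_ms, rate_hz = isis$rate_hz,
                    mean_current_na = mean_cur)
  out[!is.na(out$mean_current_na), , drop = FALSE]
}
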