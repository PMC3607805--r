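# Shared, lazily computed simulation results.  The full-scale default
# trials are expensive (~40 s each), so every test file draws them from
# this cache; the first access computes, later accesses reuse.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# one default 3 s trial of the full 2000-neuron network
default_trial <- function(seed = 1) {
  cached(paste0("default_", seed),
         run_simulation(network_config(), seed = seed))
}

# five default trials (the scaled-down multi-trial condition)
default_trials <- function(n = 5) {
  lapply(seq_len(n), default_trial)
}

# pooled excitatory instantaneous rates over the five default trials
pooled_exc_rates <- function() {
  cached("pooled_exc_rates", unlist(lapply(default_trials(), function(s)
    instantaneous_rates(s, population = "excitatory")$rate_hz)))
}

cached_lfp <- function(seed = 1) {
  cached(paste0("lfp_", seed), compute_lfp(default_trial(seed)))
}

# low-drive control (no collective rhythm expected)
low_drive_trial <- function() {
  cached("low_drive", run_simulation(
    network_config(drive = drive_params(mean_rate = 5000)), seed = 1))
}

# GABA decay-time sweep, one trial each, shared seed
cached_sweep <- function() {
  cached("sweep", tau_d_sweep(network_config(), seed = 1))
}

# small fast network for structural / determinism tests
small_trial <- function(seed = 11, n = 300, duration = 500) {
  cached(sprintf("small_%d_%d_%g", seed, n, duration),
         run_simulation(network_config(n = n, duration = duration,
                                       n_record_exc = 5, n_record_inh = 2),
                        seed = seed))
}

exc_params <- function() neuron_params("excitatory")
inh_params <- function() neuron_params("inhibitory")

cached_rheobase <- function() {
  cached("rheobase", find_rheobase(exc_params(), tol = 1e-4))
}
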