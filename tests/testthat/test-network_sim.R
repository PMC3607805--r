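# Network construction, synaptic kinetics, external drive, and the full
# simulation loop.

test_that("connectivity is Bernoulli with the right degree and delays", {
  set.seed(101)
  g <- build_connectivity(2000, p_connect = 0.1)
  deg <- diff(g$offsets)
  expect_equal(length(deg), 2000)
  se <- sqrt(2000 * 0.1 * 0.9) / sqrt(2000)
  expect_lt(abs(mean(deg) - 200), 3 * se)
  # no self-connections
  pre <- rep(seq_len(2000), deg)
  expect_true(all(pre != g$targets))
  # gamma delays moment-matched: mean 2 ms, variance 4 ms^2
  n <- length(g$delays_ms)
  expect_lt(abs(mean(g$delays_ms) - 2), 3 * 2 / sqrt(n))
  expect_lt(abs(var(g$delays_ms) - 4), 3 * sqrt(20) * 2 / sqrt(n))
  expect_true(all(g$delays_ms >= 0))
  # edge cases
  expect_equal(length(build_connectivity(50, p_connect = 0)$targets), 0)
  expect_error(build_connectivity(1), "at least 2")
  # seed reproducibility
  expect_identical(build_connectivity(100, seed = 7),
                   build_connectivity(100, seed = 7))
})

test_that("OU rate path has the configured mean, correlation time and cut-off", {
  expect_equal(ou_cutoff_hz(drive_params()), 9.9, tolerance = 0.005)
  set.seed(5)
  flat <- ou_rate_path(drive_params(sigma = 0), 1000, dt = 1)
  expect_true(all(flat$lambda == 8500))
  d <- drive_params(sigma_scale = 100)   # sd 60 spikes/s, measurable
  p <- ou_rate_path(d, 1e5, dt = 1)
  x <- p$lambda - mean(p$lambda)
  expect_lt(abs(mean(p$lambda) - 8500), 10)
  expect_lt(abs(sd(x) - 60) / 60, 0.2)
  tau_emp <- -1 / log(acf(x, lag.max = 2, plot = FALSE)$acf[2])
  expect_lt(abs(tau_emp - 16) / 16, 0.2)
  # spectrum: flat below the cut-off, falling ~1/f^2 an octave above
  psd <- multitaper_psd(x, fs = 1000, window_ms = 1000, pad = 1024)
  p_low <- mean(psd$power[psd$freq > 2 & psd$freq < 6])
  p_mid <- mean(psd$power[psd$freq > 38 & psd$freq < 42])
  p_hi <- mean(psd$power[psd$freq > 78 & psd$freq < 82])
  expect_lt(p_low / mean(psd$power[psd$freq > 0.5 & psd$freq < 2]), 3)
  expect_equal(p_mid / p_hi, 4, tolerance = 0.5)   # one octave, 1/f^2
  expect_error(ou_rate_path(drive_params(), 100, dt = 5), "tau_ou/10")
})

test_that("external Poisson trains share the rate but not the events", {
  set.seed(9)
  lam <- rep(8500, 20001)    # 1 s at dt 0.05 ms; lambda dt = 0.425 warns
  tr <- suppressWarnings(external_spike_trains(lam, 0.05, 4))
  counts <- lengths(tr)
  # per-bin Bernoulli at p = lambda dt: mean count 8500, sd ~ 70 over 1 s
  expect_true(all(abs(counts - 8500) < 300))
  expect_false(identical(tr[[1]], tr[[2]]))
  expect_warning(external_spike_trains(lam, 0.05, 1), "0.2")
  # thin-bin regime: count is Poisson(integral of lambda)
  lam2 <- rep(800, 100001)   # 1 s at dt 0.01 ms -> lambda dt = 0.008
  tr2 <- external_spike_trains(lam2, 0.01, 8)
  expect_true(all(abs(lengths(tr2) - 800) < 4 * sqrt(800)))
  expect_equal(lengths(external_spike_trains(rep(0, 1000), 0.05, 3)),
               rep(0L, 3))
})

test_that("double-exponential conductance: closed form, peak, superposition", {
  syn <- synapse_params("AMPA_recurrent")
  expect_equal(conductance_peak_time(syn),
               2 * 0.5 / 1.5 * log(4), tolerance = 1e-12)
  expect_equal(conductance_peak_time(syn), 0.924, tolerance = 1e-3)
  tt <- seq(0, 20, by = 0.05)
  g1 <- conductance_timecourse(syn, tt)
  expect_equal(which.max(g1), which.min(abs(tt - conductance_peak_time(syn))))
  # superposition: two simultaneous events double the conductance
  g2 <- conductance_timecourse(syn, tt, event_times = c(0, 0))
  expect_equal(g2, 2 * g1)
  # current reverses at E_syn
  expect_equal(synaptic_current(syn, 1, V_post = syn$E_syn), 0)
  expect_gt(synaptic_current(syn, 1, V_post = -65), 0)   # depolarising
  gab <- synapse_params("GABA")
  expect_lt(synaptic_current(gab, 3, V_post = -65), 0)   # hyperpolarising
  # event-driven accumulator recursion reproduces the closed form exactly
  dt <- 0.05
  dec_r <- exp(-dt / syn$tau_r); dec_d <- exp(-dt / syn$tau_d)
  a_r <- 1; a_d <- 1; g_ev <- numeric(length(tt)); g_ev[1] <- 0
  for (k in 2:length(tt)) {
    a_r <- a_r * dec_r; a_d <- a_d * dec_d
    g_ev[k] <- syn$g_prime * 1e-3 / (syn$tau_d - syn$tau_r) * (a_d - a_r)
  }
  expect_lt(max(abs(g_ev - g1)), 1e-10 * max(g1))
})

test_that("simulated PSP matches an independent ODE integration", {
  # dual route: event-driven Heun core vs deSolve lsoda with the
  # closed-form conductance in the right-hand side
  exc <- exc_params()
  syn <- synapse_params("AMPA_external")
  amp_pkg <- psp_amplitude(exc, syn)
  rest <- simulate_single(exc, 0, 500, record = FALSE)
  rhs <- function(t, y, parms) {
    g <- conductance_timecourse(syn, t - 20)
    Isyn <- -g * (y[1] - syn$E_syn)
    d <- cpp_derivs_wrap(y, Isyn, exc)
    list(d)
  }
  cpp_derivs_wrap <- function(y, Isyn, p)
    as.numeric(membrane_derivatives(list(V = y[1], n = y[2], h = y[3]),
                                    Isyn, p))
  sol <- deSolve::lsoda(c(rest$V_end, rest$n_end, rest$h_end),
                        seq(0, 100, by = 0.05), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  amp_ode <- max(abs(sol[, 2] - rest$V_end))
  expect_equal(amp_pkg, amp_ode, tolerance = 1e-3)
})

test_that("PSP vanishes with zero conductance", {
  expect_equal(psp_amplitude(exc_params(),
                             synapse_params("GABA", g_prime = 0)), 0)
})

test_that("network runs are seed-deterministic and spike times valid", {
  s1 <- small_trial(seed = 11)
  s2 <- run_simulation(network_config(n = 300, duration = 500,
                                      n_record_exc = 5, n_record_inh = 2),
                       seed = 11)
  expect_identical(s1$raster, s2$raster)
  expect_identical(s1$traces, s2$traces)
  s3 <- run_simulation(network_config(n = 300, duration = 500,
                                      n_record_exc = 5, n_record_inh = 2),
                       seed = 12)
  expect_false(identical(s1$raster, s3$raster))
  expect_true(all(s1$raster$time_ms >= 0 & s1$raster$time_ms <= 500))
  expect_true(all(is.finite(unlist(s1$traces))))
})

test_that("a network with no synapses and no drive is silent", {
  cfg <- network_config(n = 50, duration = 300,
    drive = drive_params(mean_rate = 0),
    synapses = list(
      ampa_recurrent = synapse_params("AMPA_recurrent", g_prime = 0),
      ampa_external = synapse_params("AMPA_external", g_prime = 0),
      gaba = synapse_params("GABA", g_prime = 0)),
    n_record_exc = 2, n_record_inh = 1)
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(sim$raster), 0)
  expect_true(all(abs(sim$mean_net) == 0))
})

test_that("default network is balanced with irregular sparse firing", {
  sim <- default_trial(1)
  rheo <- cached_rheobase()
  late <- seq_along(sim$mean_net) * sim$dt > 500
  # mean net input below threshold, external component alone above it
  expect_lt(mean(sim$mean_net[late]), rheo)
  expect_gt(mean(sim$mean_ext[late]), rheo)
  # inhibitory units fire faster than excitatory units
  re <- sum(sim$raster$population == "excitatory") / sim$n_exc
  ri <- sum(sim$raster$population == "inhibitory") / (sim$n - sim$n_exc)
  expect_gt(ri, re)
  # strongly irregular single-unit spiking
  isis <- instantaneous_rates(sim)
  cv <- tapply(isis$isi_ms, isis$neuron,
               function(x) if (length(x) > 5) sd(x) / mean(x) else NA)
  expect_gt(median(cv, na.rm = TRUE), 0.8)
})

test_that("trials with different seeds are statistically exchangeable", {
  # ISIs within a trial are dependent (within-neuron and network-wide
  # co-fluctuations), which makes a full-sample KS test anti-conservative;
  # subsampling restores an approximately independent comparison
  set.seed(17)
  i1 <- sample(instantaneous_rates(default_trial(1))$isi_ms, 1000)
  i2 <- sample(instantaneous_rates(default_trial(2))$isi_ms, 1000)
  ks <- suppressWarnings(stats::ks.test(i1, i2))
  expect_gt(ks$p.value, 0.01)
})
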