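# Single-cell model: gating kinetics, membrane equation, f-I curve,
# rheobase, phase response.

test_that("gating rate constants match the printed closed forms", {
  # exponent-zero cases
  expect_equal(gating_rates(-30, "n")$beta, 0.125)
  expect_equal(gating_rates(-41, "m")$beta, 4)
  expect_equal(gating_rates(0, "h")$beta, 0.5)
  # removable singularities evaluated by their analytic limits
  expect_equal(gating_rates(-20, "n")$alpha, 0.1)
  expect_equal(gating_rates(-16, "m")$alpha, 1.0)
  # continuity across the singular voltages
  for (v in c(-20, -16)) {
    g <- if (v == -20) "n" else "m"
    left <- gating_rates(v - 1e-4, g)$alpha
    right <- gating_rates(v + 1e-4, g)$alpha
    expect_lt(abs(left - right), 1e-4)
  }
  # generic values against direct evaluation of the formulas
  V <- c(-75.3, -52.1, -10)
  expect_equal(vapply(V, function(v) gating_rates(v, "n")$alpha, 1),
               0.01 * (V + 20) / (1 - exp(-(V + 20) / 10)))
  expect_equal(vapply(V, function(v) gating_rates(v, "h")$alpha, 1),
               0.07 * exp(-(V + 30) / 20))
  expect_error(gating_rates(NaN, "n"), "finite")
})

test_that("rates stay non-negative over the physiological voltage range", {
  for (g in c("n", "m", "h")) for (v in seq(-100, 60, by = 1)) {
    rc <- gating_rates(v, g)
    expect_gte(rc$alpha, 0)
    expect_gte(rc$beta, 0)
  }
})

test_that("steady-state sodium activation is a sigmoid with the right limits", {
  v <- seq(-100, 60, by = 0.5)
  m <- m_infinity(v)
  expect_true(all(m > 0 & m < 1))
  expect_true(all(diff(m) > 0))
  expect_lt(m_infinity(-100), 1e-4)
  expect_gt(m_infinity(60), 0.995)
  # direct evaluation of the printed formulas at the alpha_m singularity:
  # alpha_m(-16) = 1, beta_m(-16) = 4 exp(-25/18)
  expect_equal(m_infinity(-16), 1 / (1 + 4 * exp(-25 / 18)), tolerance = 1e-10)
})

test_that("membrane derivatives follow the conductance-based equation", {
  exc <- exc_params()
  # leak term vanishes at V_L with gates shut and no input
  d <- membrane_derivatives(list(V = exc$V_L, n = 0, h = 0), 0, exc)
  expect_equal(unname(d["dV"]), 0)
  # linearity in the input current: dV/dt shifts by I / C_m
  st <- list(V = -60, n = 0.3, h = 0.6)
  d0 <- membrane_derivatives(st, 0, exc)
  d1 <- membrane_derivatives(st, 1, exc)
  expect_equal(unname(d1["dV"] - d0["dV"]), 1 / exc$C_m)  # 4 mV/ms
  # the resting state is a fixed point: all derivatives vanish
  rest <- simulate_single(exc, 0, 1000, record = FALSE)
  dr <- membrane_derivatives(list(V = rest$V_end, n = rest$n_end,
                                  h = rest$h_end), 0, exc)
  expect_true(all(abs(dr) < 1e-5))
})

test_that("subthreshold dynamics: rest is stable, gating stays in [0,1]", {
  exc <- exc_params()
  s <- simulate_single(exc, 0, 500)
  expect_length(s$spikes, 0)
  expect_lt(abs(s$V_end - exc$V_L), 0.1)
  # a 1 mV perturbation decays without a spike
  p <- simulate_single(exc, 0, 200, V0 = s$V_end + 1, n0 = s$n_end,
                       h0 = s$h_end)
  expect_length(p$spikes, 0)
  expect_lt(abs(p$V_end - s$V_end), 0.01)
  # gating bounds along a spiking trajectory
  sp <- simulate_single(exc, 1.2, 500)
  expect_true(all(sp$n >= -1e-6 & sp$n <= 1 + 1e-6))
  expect_true(all(sp$h >= -1e-6 & sp$h <= 1 + 1e-6))
})

test_that("tonic firing is periodic and converged in the time step", {
  exc <- exc_params()
  s <- simulate_single(exc, 1.2, 2000, record = FALSE)
  isi <- diff(s$spikes[s$spikes > 500])
  expect_gt(length(isi), 50)
  expect_lt(sd(isi) / mean(isi), 0.01)
  # moderately suprathreshold drive (~91 spikes/s): halving the step
  # changes the steady period by < 0.5% (the stiff spike upstroke makes
  # the period the slowest-converging observable)
  s1 <- simulate_single(exc, 0.9, 2000, record = FALSE)
  s2 <- simulate_single(exc, 0.9, 2000, dt = 0.025, record = FALSE)
  p1 <- mean(diff(s1$spikes[s1$spikes > 500]))
  p2 <- mean(diff(s2$spikes[s2$spikes > 500]))
  expect_lt(abs(p1 - p2) / p2, 0.005)
})

test_that("integration failure is reported on blow-up", {
  bad <- neuron_params("excitatory", g_Na = 12.5, C_m = 0.25)
  expect_error(simulate_single(bad, 1e4, 100, record = FALSE),
               "integration failure")
})

test_that("Heun scheme shows second-order convergence", {
  exc <- exc_params()
  endV <- function(dt) simulate_single(exc, I_const = 0.3, duration = 100,
                                       dt = dt, V0 = -72,
                                       record = FALSE)$V_end
  ref <- endV(0.0005)
  e <- abs(c(endV(0.1), endV(0.05), endV(0.025)) - ref)
  expect_equal(e[1] / e[2], 4, tolerance = 0.15)
  expect_equal(e[2] / e[3], 4, tolerance = 0.15)
})

test_that("both cell classes share the rheobase; f-I is type I", {
  exc <- exc_params(); inh <- inh_params()
  re <- cached_rheobase()
  ri <- find_rheobase(inh, tol = 1e-4)
  expect_lt(abs(re - ri), 2e-4)
  # below threshold: silent; above: fires
  expect_equal(.steady_rate(exc, re - 2e-4, 2000, 500, 0.05), 0)
  expect_gt(.steady_rate(exc, re + 2e-4, 2000, 500, 0.05), 0)
  # type-I signature: arbitrarily low rates just above rheobase
  fine <- f_i_curve(exc, re + c(2e-4, 5e-4, 1e-3), duration = 3000,
                    discard = 500)
  nz <- fine$rate_hz[fine$rate_hz > 0]
  expect_gt(length(nz), 0)
  expect_lt(min(nz), 5)
})

test_that("f-I curves are nondecreasing and faster for inhibitory cells", {
  grid <- seq(0.6, 1.6, by = 0.2)
  fe <- f_i_curve(exc_params(), grid, duration = 1500)
  fi <- f_i_curve(inh_params(), grid, duration = 1500)
  expect_true(all(diff(fe$rate_hz) >= 0))
  expect_true(all(diff(fi$rate_hz) >= 0))
  sup <- fe$rate_hz > 0
  expect_true(all(fi$rate_hz[sup] > fe$rate_hz[sup]))
})

test_that("phase response to a depolarising pulse is a pure advance", {
  exc <- exc_params()
  # null pulse: shifts at measurement-noise level only
  p0 <- phase_response_curve(exc, I_drive = 1.0, pulse_amp = 0,
                             n_phases = 16)
  expect_true(all(abs(p0$phase_shift) < 5e-3))
  # the operating point is set by the target period, not a guessed current
  prc <- phase_response_curve(exc, target_period = 8.09, n_phases = 32)
  expect_equal(prc$T0, 8.09, tolerance = 0.01)
  expect_true(all(prc$phase_shift >= -5e-3))
  expect_gt(max(prc$phase_shift), 0.02)
  # a pulse just before the next spike can barely advance it
  late <- prc$phase_shift[prc$phase > 0.95]
  expect_true(all(late < 0.02))
  prc_i <- phase_response_curve(inh_params(), target_period = 6.00,
                                n_phases = 32)
  expect_equal(prc_i$T0, 6.00, tolerance = 0.01)
  # pure advance once the pulse falls outside the action potential
  # itself; a pulse landing on the spike can lengthen the cycle slightly
  out_ap <- prc_i$phase > 0.05 & prc_i$phase < 0.95
  expect_true(all(prc_i$phase_shift[out_ap] >= -5e-3))
  expect_gt(min(prc_i$phase_shift), -0.02)
})

test_that("derived membrane constants follow from the presets", {
  expect_equal(membrane_time_constant(exc_params()), 10)
  expect_equal(membrane_time_constant(inh_params()), 5)
  expect_equal(round(temperature_factor(34)), 21)
  expect_equal(exc_params()$phi, 21)
})
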