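# Single-compartment conductance-based neuron model: membrane equation,
# gating kinetics, and single-cell characterisation (f-I curve, rheobase,
# phase response curve).

#' Neuron parameter presets
#'
#' Returns the parameter set of the type-I conductance-based membrane model
#' used throughout the package.  Both cell classes share all channel
#' parameters; only the membrane capacitance differs, so the excitatory
#' membrane time constant \eqn{\tau_m = C_m/g_L} is 10 ms and the inhibitory
#' one 5 ms.
#'
#' @param population `"excitatory"` or `"inhibitory"`.
#' @param C_m Membrane capacitance (nF). Defaults to 0.25 (excitatory) or
#'   0.125 (inhibitory).
#' @param g_K,g_Na,g_L Maximal potassium, sodium and leak conductances (uS).
#' @param V_K,V_Na,V_L Reversal potentials (mV).
#' @param temperature_T Temperature in degrees Celsius (34 by default).
#' @param phi Temperature factor scaling the gating kinetics. The default,
#'   21, is the rounded value of `3^((temperature_T - 6.3)/10)` at 34 C
#'   (see [temperature_factor()]).
#' @return An object of class `neuron_params`.
#' @seealso [membrane_time_constant()], [simulate_single()]
#' @export
neuron_params <- function(population = c("excitatory", "inhibitory"),
                          C_m = NULL,
                          g_K = 4.74, g_Na = 12.5, g_L = 0.025,
                          V_K = -80, V_Na = 40, V_L = -65,
                          temperature_T = 34, phi = 21) {
  population <- match.arg(population)
  if (is.null(C_m)) C_m <- if (population == "excitatory") 0.25 else 0.125
  stopifnot(g_K > 0, g_Na > 0, g_L > 0, C_m > 0, phi > 0)
  structure(
    list(label = population, C_m = C_m,
         g_K = g_K, g_Na = g_Na, g_L = g_L,
         V_K = V_K, V_Na = V_Na, V_L = V_L,
         temperature_T = temperature_T, phi = phi),
    class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %s: C_m = %g nF, tau_m = %g ms, phi = %g\n",
              x$label, x$C_m, membrane_time_constant(x), x$phi))
  invisible(x)
}

#' Membrane time constant
#'
#' \eqn{\tau_m = C_m / g_L}, in ms.
#' @param params A [neuron_params()] object.
#' @export
membrane_time_constant <- function(params) params$C_m / params$g_L

#' Temperature factor of the gating kinetics
#'
#' \eqn{\phi = 3^{(T - 6.3)/10}} with `T` in degrees Celsius.
#' @param temperature_T Temperature (C).
#' @export
temperature_factor <- function(temperature_T) 3^((temperature_T - 6.3) / 10)

# parameter vector handed to the C++ core
.np_vec <- function(params) {
  c(params$C_m, params$phi, params$g_K, params$g_Na, params$g_L,
    params$V_K, params$V_Na, params$V_L)
}

.np_shared <- function(params) .np_vec(params)[-1]

#' Voltage-dependent gating rate constants
#'
#' Opening (`alpha`) and closing (`beta`) rates, in 1/ms, for the potassium
#' activation gate `n`, the sodium activation gate `m`, or the sodium
#' inactivation gate `h`.  The removable singularities of `alpha_n` at
#' V = -20 mV and `alpha_m` at V = -16 mV are evaluated by their analytic
#' limits (0.1 and 1.0 respectively).
#'
#' @param V Membrane potential (mV), finite scalar.
#' @param gate One of `"n"`, `"m"`, `"h"`.
#' @return A list with `alpha`, `beta` (1/ms) and `gate`.
#' @export
gating_rates <- function(V, gate = c("n", "m", "h")) {
  gate <- match.arg(gate)
  if (!is.numeric(V) || length(V) != 1L || !is.finite(V))
    stop("`V` must be a finite numeric scalar (mV)")
  ab <- cpp_gating_rates(V, match(gate, c("n", "m", "h")) - 1L)
  list(alpha = unname(ab["alpha"]), beta = unname(ab["beta"]), gate = gate)
}

#' Steady-state sodium activation
#'
#' \eqn{m_\infty(V) = \alpha_m / (\alpha_m + \beta_m)}.  The activation gate
#' `m` is much faster than the membrane dynamics and is replaced by this
#' steady state in the membrane equation.
#'
#' @param V Membrane potential (mV); vectorised.
#' @export
m_infinity <- function(V) {
  if (any(!is.finite(V))) stop("`V` must be finite (mV)")
  vapply(V, cpp_m_inf, numeric(1))
}

#' Steady-state gating variables n and h
#'
#' @param V Membrane potential (mV), scalar.
#' @return Named vector with `n` and `h` at steady state.
#' @export
gating_steady_state <- function(V) {
  if (!is.finite(V)) stop("`V` must be finite (mV)")
  cpp_gating_steady(V)
}

#' Membrane and gating time-derivatives
#'
#' Right-hand side of the conductance-based membrane model
#' \deqn{C_m dV/dt = -g_K n^4 (V - V_K) - g_{Na} m_\infty^3 h (V - V_{Na})
#'   - g_L (V - V_L) + I_{syn},}
#' with first-order gating kinetics scaled by the temperature factor
#' \eqn{\phi}.
#'
#' @param state List or named vector with `V` (mV), `n`, `h`.
#' @param I_syn Synaptic/injected current (nA).
#' @param params A [neuron_params()] object.
#' @return Named vector `dV` (mV/ms), `dn`, `dh` (1/ms).
#' @export
membrane_derivatives <- function(state, I_syn, params) {
  state <- as.list(state)
  stopifnot(state$n >= 0, state$n <= 1, state$h >= 0, state$h <= 1)
  cpp_derivs(state$V, state$n, state$h, I_syn, .np_vec(params))
}

#' Simulate a single neuron
#'
#' Integrates the membrane model with the Heun (predictor-corrector) scheme
#' at a fixed time step.  Input is a constant current, optionally augmented
#' by a rectangular current pulse and/or a train of double-exponential
#' conductance events through one synapse.  Spikes are detected as upward
#' crossings of `v_th` (default 0 mV, unambiguous for full-amplitude sodium
#' spikes) with a 2 ms lockout; spike times are linearly interpolated
#' between grid points.
#'
#' @param params A [neuron_params()] object.
#' @param I_const Constant injected current (nA).
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms), default 0.05.
#' @param V0 Initial potential (mV); gating starts at its steady state for
#'   `V0` unless `n0`/`h0` are given.
#' @param n0,h0 Optional initial gating values in `[0, 1]`.
#' @param pulse Optional list `list(amp, start, dur)`: rectangular current
#'   pulse (nA, ms, ms).
#' @param syn Optional list `list(times, g_prime, tau_r, tau_d, E_syn)`
#'   describing conductance events (times in ms, `g_prime` in uS).
#' @param v_th Spike detection threshold (mV).
#' @param lockout Spike detection dead time (ms).
#' @param record If `TRUE` (default), return the full `V`, `n`, `h` traces.
#' @return List with `spikes` (ms), `time`, and (if recorded) `V`, `n`, `h`.
#' @export
simulate_single <- function(params, I_const = 0, duration = 1000, dt = 0.05,
                            V0 = params$V_L, n0 = NULL, h0 = NULL,
                            pulse = NULL, syn = NULL,
                            v_th = 0, lockout = 2, record = TRUE) {
  stopifnot(dt > 0, duration > 10 * dt)
  pa <- if (is.null(pulse)) 0 else pulse$amp
  ps <- if (is.null(pulse)) 0 else pulse$start
  pd <- if (is.null(pulse)) 0 else pulse$dur
  st <- if (is.null(syn)) numeric(0) else syn$times
  sg <- if (is.null(syn)) 0 else syn$g_prime
  sr <- if (is.null(syn)) 1 else syn$tau_r
  sd_ <- if (is.null(syn)) 2 else syn$tau_d
  sE <- if (is.null(syn)) 0 else syn$E_syn
  if (!is.null(syn)) stopifnot(sd_ > sr, sr > 0)
  out <- cpp_simulate_single(.np_vec(params), V0,
                             if (is.null(n0)) -1 else n0,
                             if (is.null(h0)) -1 else h0,
                             I_const, duration, dt, pa, ps, pd,
                             st, sg, sr, sd_, sE, v_th, lockout, record)
  out$time <- seq(0, by = dt, length.out = round(duration / dt) + 1)
  out$dt <- dt
  out
}

#' Steady-state firing frequency under constant current
#'
#' Frequency (spikes/s) from the mean interspike interval after discarding
#' an initial transient; 0 if fewer than two spikes survive the transient.
#' @keywords internal
.steady_rate <- function(params, I, duration, discard, dt) {
  sim <- simulate_single(params, I_const = I, duration = duration, dt = dt,
                         record = FALSE)
  s <- sim$spikes[sim$spikes > discard]
  if (length(s) < 2) return(0)
  1000 / mean(diff(s))
}

#' f-I curve
#'
#' Steady-state firing frequency as a function of injected current.  The
#' model is type I: frequency rises continuously from zero at rheobase, so
#' arbitrarily low rates are attainable just above threshold.
#'
#' @param params A [neuron_params()] object.
#' @param currents Ascending grid of injected currents (nA).
#' @param duration,discard Simulation length and discarded transient (ms).
#' @param dt Integration step (ms).
#' @return Object of class `fi_curve`: data.frame with `current_nA` and
#'   `rate_hz`.
#' @export
f_i_curve <- function(params, currents, duration = 2000, discard = 500,
                      dt = 0.05) {
  stopifnot(!is.unsorted(currents))
  rates <- vapply(currents, function(I)
    .steady_rate(params, I, duration, discard, dt), numeric(1))
  structure(data.frame(current_nA = currents, rate_hz = rates),
            class = c("fi_curve", "data.frame"),
            population = params$label)
}

#' Rheobase by bisection
#'
#' Minimal constant current producing sustained spiking, located by
#' bisection on a "fires throughout a 2 s window" predicate.  Because the
#' spiking onset is a saddle-node-on-invariant-circle bifurcation of the
#' voltage equation alone, the rheobase does not depend on the membrane
#' capacitance: excitatory and inhibitory presets share the same threshold.
#'
#' @param params A [neuron_params()] object.
#' @param tol Bracket width at termination (nA).
#' @param bracket Initial search interval (nA).
#' @param duration Test-simulation length (ms).
#' @param dt Integration step (ms).
#' @return Estimated rheobase (nA), the midpoint of the final bracket.
#' @export
find_rheobase <- function(params, tol = 1e-4, bracket = c(0, 1),
                          duration = 2000, dt = 0.05) {
  stopifnot(tol > 0, length(bracket) == 2, bracket[1] < bracket[2])
  fires <- function(I) {
    sim <- simulate_single(params, I_const = I, duration = duration, dt = dt,
                           record = FALSE)
    # sustained: spiking persists into the second half of the window
    length(sim$spikes) >= 2 && max(sim$spikes) > duration / 2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo) || !fires(hi))
    stop("rheobase bracket not found in [", lo, ", ", hi, "] nA")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Current producing a given tonic period
#'
#' Bisects the injected current until the steady interspike interval matches
#' `period` (ms) to within `tol`.  Used to set the operating point of phase
#' response curves when the period, not the current, is specified.
#'
#' @param params A [neuron_params()] object.
#' @param period Target unperturbed period (ms).
#' @param tol Period tolerance (ms).
#' @param bracket Current search interval (nA).
#' @param dt Integration step (ms).
#' @return Injected current (nA).
#' @export
current_for_period <- function(params, period, tol = 0.01,
                               bracket = c(0.1, 5), dt = 0.05) {
  per <- function(I) {
    sim <- simulate_single(params, I_const = I, duration = 600, dt = dt,
                           record = FALSE)
    s <- sim$spikes[sim$spikes > 200]
    if (length(s) < 5) return(Inf)
    mean(diff(s))
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (per(lo) < period || per(hi) > period)
    stop("period ", period, " ms not bracketed by currents [",
         lo, ", ", hi, "] nA")
  repeat {
    mid <- (lo + hi) / 2
    p <- per(mid)
    if (abs(p - period) <= tol || (hi - lo) < 1e-7) return(mid)
    if (p > period) lo <- mid else hi <- mid
  }
}

#' Phase response curve
#'
#' Perturbs a tonically firing neuron with a brief depolarising current
#' pulse at `n_phases` equally spaced phases of its cycle and reports the
#' normalised phase shift \eqn{1 - T(\tau)/T_0}, where \eqn{T_0} is the
#' unperturbed period and \eqn{T(\tau)} the duration of the perturbed cycle.
#' For this type-I model the shift is non-negative at every phase: a
#' depolarising pulse can only advance the next spike.
#'
#' @param params A [neuron_params()] object.
#' @param I_drive Constant drive current (nA) placing the cell in the tonic
#'   regime.  If `NULL`, `target_period` must be given and the drive is
#'   found with [current_for_period()].
#' @param target_period Optional target unperturbed period (ms).
#' @param pulse_amp,pulse_dur Pulse amplitude (nA) and duration (ms);
#'   defaults 1.0 nA and 0.2 ms.
#' @param n_phases Number of perturbation phases (>= 16).
#' @param dt Integration step (ms).
#' @return Object of class `prc_result`: list with `T0` (ms),
#'   `phase` (fractions of the period in `[0,1)`), `phase_shift`, and
#'   `I_drive` (nA).
#' @export
phase_response_curve <- function(params, I_drive = NULL, target_period = NULL,
                                 pulse_amp = 1.0, pulse_dur = 0.2,
                                 n_phases = 32, dt = 0.05) {
  stopifnot(n_phases >= 16)
  if (is.null(I_drive)) {
    if (is.null(target_period))
      stop("give either `I_drive` or `target_period`")
    I_drive <- current_for_period(params, target_period, dt = dt)
  }
  base <- simulate_single(params, I_const = I_drive, duration = 600, dt = dt,
                          record = FALSE)
  s <- base$spikes[base$spikes > 200]
  if (length(s) < 10)
    stop("drive current ", I_drive, " nA does not give tonic firing")
  T0 <- mean(diff(s))
  ref <- s[length(s) - 5]           # late spike, transient long gone
  phases <- (seq_len(n_phases) - 1) / n_phases
  shift <- vapply(phases, function(fr) {
    t_pulse <- ref + fr * T0
    per <- simulate_single(params, I_const = I_drive,
                           duration = ref + 3 * T0, dt = dt,
                           pulse = list(amp = pulse_amp, start = t_pulse,
                                        dur = pulse_dur),
                           record = FALSE)
    sp <- per$spikes
    prev <- max(sp[sp <= t_pulse + 1e-9])
    nxt <- min(sp[sp > t_pulse + 1e-9])
    1 - (nxt - prev) / T0
  }, numeric(1))
  structure(list(T0 = T0, phase = phases, phase_shift = shift,
                 I_drive = I_drive, pulse_amp = pulse_amp,
                 pulse_dur = pulse_dur),
            class = "prc_result")
}

#' Write a two-column curve as annotated CSV
#'
#' Writes f-I curves, PRCs or spectra as CSV with `#`-prefixed header
#' comments recording parameters.
#'
#' @param x A data.frame (or `prc_result`).
#' @param path Output file.
#' @param comments Character vector of annotation lines.
#' @export
write_curve_csv <- function(x, path, comments = character(0)) {
  if (inherits(x, "prc_result"))
    x <- data.frame(phase = x$phase, phase_shift = x$phase_shift)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}
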