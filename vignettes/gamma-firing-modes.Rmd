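---
title: "Balanced E/I networks, gamma rhythms, and bimodal firing modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced E/I networks, gamma rhythms, and bimodal firing modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eigamma)
```

## The scientific problem

Sensory stimulation drives primary cortical areas into narrow-band
gamma (30--90 Hz) oscillations that are visible in mesoscopic signals such
as the local field potential (LFP), while the individual neurons fire
sparsely and irregularly, at rates well below the population rhythm.
`eigamma` implements a minimal mechanistic model of this *synchronous
irregular* regime -- a balanced random network of type-I conductance-based
neurons -- together with the complete analysis chain needed to characterise
a striking emergent property: once embedded in the network, neurons whose
isolated f-I curve is continuous develop a *bimodal* distribution of
instantaneous firing rates, with a band of quasi-forbidden rates separating
a sparse, slow mode from a fast, bursty mode.  The two modes carry
different codes: fast bursts track rapid fluctuations of the external
input (a rate code), while slow isolated spikes lock to the phase of the
gamma cycle (a phase code).

## The model

### Single cells

Each neuron is a single compartment obeying

$$C_m \dot V = -g_K n^4 (V - V_K) - g_{Na} m_\infty^3 h\,(V - V_{Na})
  - g_L (V - V_L) + I_{syn},$$

with first-order gating kinetics
$\dot x = \phi\,[\alpha_x(V)(1 - x) - \beta_x(V)\,x]$ for $x \in \{n, h\}$;
the fast sodium activation $m$ is slaved to its steady state
$m_\infty = \alpha_m / (\alpha_m + \beta_m)$.  The rate functions
$\alpha_n, \beta_n, \alpha_m, \beta_m, \alpha_h, \beta_h$ are the standard
squid-like closed forms exposed by `gating_rates()`; their removable
singularities (at $-20$ mV for $\alpha_n$, $-16$ mV for $\alpha_m$) are
evaluated by a first-order series within $10^{-6}$ mV of the singular
voltage, because the naive expressions are 0/0 there.

Units are fixed package-wide to mV, ms, nA, $\mu$S and nF, so conductance
times voltage is current in nA and $\dot V = I/C_m$ is mV/ms.  Synaptic
conductance scales quoted in nS are converted internally.

Default parameters: $g_K = 4.74$, $g_{Na} = 12.5$, $g_L = 0.025\ \mu$S;
$V_K = -80$, $V_{Na} = 40$, $V_L = -65$ mV; $\phi = 21$ (34 °C); and
$C_m = 0.25$ nF for excitatory cells vs $0.125$ nF for inhibitory ones,
giving membrane time constants of 10 and 5 ms.  Both classes share all
channel parameters, so they share the rheobase exactly (the spiking onset
is a saddle-node-on-invariant-circle bifurcation of the voltage equation,
in which $C_m$ plays no part), but the lighter inhibitory membrane fires
faster at any suprathreshold current.  The excitability is type I:
`f_i_curve()` rises continuously from zero above rheobase, and
`phase_response_curve()` is non-negative at every phase outside the
action potential itself -- a depolarising pulse can only advance the next
spike (a pulse landing on the spike's downstroke can lengthen the cycle
by under 1% of the period; the advance property concerns the oscillation
phase, not perturbations of the spike waveform).

The pulse used for phase-response curves (1 nA, 0.2 ms) is applied at an
operating point specified by the unperturbed *period* (8.09 ms excitatory,
6.00 ms inhibitory); because the matching drive current is not itself a
model parameter, `current_for_period()` bisects the current until the
tonic period matches to 0.01 ms rather than guessing a current.

### Network

2000 neurons, 80% excitatory, each ordered pair connected independently
with probability 0.1 (mean out-degree 200; no self-connections, no further
structure).  Synapses are conductance-based double exponentials

$$g_{syn}(t) = \frac{g'_{syn}}{\tau_d - \tau_r}
 \left[e^{-(t-t_j)/\tau_d} - e^{-(t-t_j)/\tau_r}\right],\qquad
 I_{syn} = -g_{syn}(V - E_{syn}),$$

with AMPA kinetics 0.5/2 ms ($E = 0$ mV) and GABA kinetics 2/5 ms
($E = -70$ mV); conductance scales are 2.5 nS (recurrent AMPA), 3.2 nS
(external AMPA) and 240 nS (GABA) onto both target classes.  Recurrent
spikes arrive after a gamma-distributed axonal delay (mean 2 ms, variance
4 ms$^2$; moment-matched shape 1, scale 2 ms), snapped to the integration
grid; external events carry no delay.

Every neuron additionally receives an independent Poisson train of
external AMPA events whose common instantaneous rate is an
Ornstein--Uhlenbeck process around 8500 spikes/s with correlation time
16 ms (spectral cut-off $1/2\pi\tau \approx 9.9$ Hz) and stationary
standard deviation 0.6 spikes/s.  That printed standard deviation is
minute relative to the mean; `drive_params()` therefore exposes a
`sigma_scale` multiplier (default 1, i.e. the printed value) so analyses
that need *visible* drive fluctuations -- the external-rate coding scatter
-- can scale the fluctuation up explicitly instead of silently
reinterpreting a constant.

### Integration

All state variables advance with the Heun predictor--corrector scheme at
$dt = 0.05$ ms (verified second order: halving $dt$ reduces the endpoint
error of a subthreshold trajectory fourfold).  The OU drive uses the
stochastic Heun variant with the same Wiener increment in predictor and
corrector, which for this linear additive-noise equation reduces to an
exact linear recursion.  Synaptic conductances are tracked by paired
rise/decay accumulators that decay exponentially between events and gain
+1 per arriving event; this reproduces the closed-form double exponential
to machine precision and makes the per-step cost independent of the event
history.  Inside the network core the external train is drawn as per-step
Poisson *counts* (exact for any $\lambda\,dt$); the Bernoulli-thinning
generator `external_spike_trains()` is provided for fixture work and warns
when $\lambda\,dt > 0.2$.  Spikes are detected as upward crossings of
0 mV -- unambiguous for full-amplitude sodium spikes -- with a 2 ms
lockout, and spike *times* are linearly interpolated at the crossing,
which removes grid quantisation from ISI statistics.  A trial is 3 s;
connectivity, initial conditions ($V$ uniform in $[V_L - 5, V_L]$, gating
at steady state) and all noise are redrawn per trial from one seed, and
runs are bitwise reproducible.

## Observables

The LFP proxy is $R_e \langle |I_{AMPA}| + |I_{GABA}| \rangle$ with
$R_e = 1$ M$\Omega$: the absolute synaptic currents (external plus
recurrent AMPA, and GABA) are averaged over the excitatory population --
absolute value per neuron first, then the population mean, reading the
angle brackets literally.  The average is accumulated on the integration
grid and downsampled by averaging to 1 ms bins, so a 500 ms analysis
window holds 500 samples and zero-padding to 512 is meaningful.  The
population rate is a 1 ms spike-time histogram normalised per neuron and
per second.  The embedded f-I scatter pairs each interspike interval's
instantaneous rate with the net synaptic current averaged over the open
interval between the two spikes, excluding 1 ms on each side so the
spike-current artefacts do not bias the mean.

Power spectra use the multitaper estimator: 500 ms windows sliding with
50 ms overlap, demeaned per window, multiplied by $K = 5$ Slepian tapers,
zero-padded to 512 samples, with power averaged over tapers, windows and
trials in fixed trial order.  The tapers come from the standard
tridiagonal commuting-matrix eigenproblem and are validated against an
independent implementation to $10^{-14}$.  The time-bandwidth product is
$NW = 3$; it is not an independent choice, since $K = 5 = 2NW - 1$ and the
resolution half-bandwidth $NW/T = 6$ Hz must both hold.  Band-pass
filtering is a 4th-order Butterworth around $46.88 \pm 5$ Hz applied
forward--backward by default, so filtering does not shift spike--phase
relations; a single-pass mode (with its group delay) is available behind
`zero_phase = FALSE` for strict replication of one-pass processing.  The
instantaneous phase is the angle of the analytic (Hilbert) signal, with
maxima at 0 and troughs at $\pi$, interpolated linearly (after
unwrapping) at spike times.

`spectral_peak()` must distinguish a genuine gamma line from the
$1/f$-type background.  It fits a robust log--log trend to the spectrum
outside the search band and flags a peak only when the in-band arg-max is
a local maximum exceeding the trend by more than 4 robust standard
deviations of the out-of-band residuals.  The threshold was calibrated on
synthetic $1/f^2$ noise to keep the false-positive rate below 5% over 100
realisations; the default network's gamma peak clears it by a factor of
two or more, while the low-drive (5000 spikes/s) condition stays below
it.

## Firing-mode analyses

Instantaneous rates (1/ISI) are pooled per population, log-transformed,
and smoothed with a Gaussian KDE at the Silverman bandwidth.  The
slow/fast *frontier* is the density minimum between the two largest
modes; reading a histogram minimum by eye is not reproducible, so this
estimator is the package's fixed convention.  Unimodal samples must fail:
the gate is Silverman's critical-bandwidth bootstrap test (no dip-test
implementation is available in the environment, and the critical-bandwidth
test serves the same purpose), and failures raise a typed
`eig_no_frontier` condition.

Spikes are classified by their flanking intervals: an ISI faster than the
frontier is fast, a spike flanking any fast ISI is fast, a spike flanking
only slow ISIs is slow, and a *burst-first* spike is a fast spike whose
preceding ISI is slow or absent (the first spike of a maximal run of fast
ISIs).  Spike-triggered averages use a window from 50 ms before to 20 ms
after the spike and admit only spikes whose same-neuron predecessor is at
least 50 ms away, so the window cannot contain the neuron's previous
spike; for the fast mode the burst-first spikes are used, because burst
initiation is the event of interest.  The STA of the LFP is global; the
STA of $I_{GABA}$ uses each spiking neuron's own afferent inhibitory
current (recorded for a 125-neuron subset), a local signal; note
$I_{GABA} \le 0$ in the package's sign convention, so stronger inhibition
is more negative.  Phase histograms use the first spikes of fast runs and
of slow ISIs, normalised per mode (per-mode normalisation is a
convention; the histograms are compared by shape and circular mean, which
are normalisation-invariant).

The *forbidden gap* is quantified on the period axis, where the
underlying mechanism -- post-spike inhibitory suppression whose duration
follows the GABA decay time -- acts: ISIs are split at the frontier and
the gap runs from the fast mode's 95th ISI percentile to the slow mode's
5th percentile.  A density-threshold width on the *rate* axis was tried
first and rejected: it shrinks as $\tau_d$ grows (the whole rate
distribution compresses downward), contradicting the mechanism the
statistic is meant to expose, whereas the period-axis quantile gap widens
with slower inhibition, as expected.

When sweeping $\tau_d$ (`tau_d_sweep()`), all conditions share one seed so
that connectivity, initial conditions and drive realisation are identical
and only the synaptic kinetics differ.  At $\tau_d = 30$ ms the rate
distribution may no longer yield a frontier of its own; mode fractions
then fall back to the reference ($\tau_d = 5$ ms) frontier, which is
reported alongside.

## Synthetic fixtures

Every analysis stage is testable without the network through generators
that return their own ground truth:

* `make_toy_lfp()`: a cosine line of controlled SNR on a $1/f^2$
  background shaped in the frequency domain, with the line's exact trough
  times as truth -- exercises the multitaper estimator, the peak flag, the
  band-pass filter and the Hilbert phase.
* `make_locked_spiketrain()`: an inhomogeneous Poisson train with
  von-Mises-type intensity $\propto e^{\kappa\cos(\phi - \phi_0)}$
  (normalised by $I_0(\kappa)$ to preserve the mean rate) plus the exact
  phase trace -- exercises phase histograms and circular statistics.
* `make_bimodal_isi_train()`: i.i.d. ISIs from a two-component lognormal
  mixture; on the rate axis the density is again a lognormal mixture whose
  closed form is minimised numerically for the true inter-mode minimum
  -- exercises frontier detection and the slow-fraction statistic.  The
  lognormal family was chosen only for positive support and controllable
  modes; no parametric ISI model is implied for the network.

The fixtures emulate the *statistics* the analyses consume, not the
conductance dynamics: passing fixture tests shows the estimators recover
known structure, and passing network tests shows the simulator produces
that structure, but neither implies the model captures features of real
recordings beyond those statistics (no spike sorting noise, no electrode
filtering, no non-stationarity).

## Problem sizes and reproduction

The package's standard reproduction (tests and `scripts/acceptance.R`)
uses the full 2000-neuron network and 3 s trials, with 5 trials for the
pooled statistics and single trials for the sweep and phase analyses:
sizes at which every headline quantity is already stable (per-trial
slow-side fractions vary by about one percentage point around 65%, and
per-trial frontiers by about 1 spike/s).  `experiment_manifest(trials =
20)` extends the trial averaging when tighter pooled estimates are
wanted.

With the default seed the package reproduces, from scratch: an LFP
multitaper peak at ~45 Hz under 8500 spikes/s drive and no significant
peak at 5000 spikes/s; a population-rate spectrum peaking at the same
frequency; a bimodal excitatory rate distribution with frontier near
58 spikes/s and ~64--66% of ISIs on the slow side; disappearance of the
rhythm with fast-mode dominance at $\tau_d = 30$ ms; and phase locking of
slow-mode inhibitory spikes near the LFP troughs ($\pi$, with a delay set
by the synaptic delay) versus burst-first excitatory spikes near the
peaks (0).

## Known limitations

* The PSP calibration ranges quoted for the original parameter set
  (0.42--0.83 mV excitatory, 1.54--1.88 mV inhibitory) are met by events
  onto *excitatory* targets but exceeded by ~6--13% onto *inhibitory*
  targets, whose membrane (half the capacitance at equal leak) is twice
  as responsive; no printed parameter combination reconciles the
  inhibitory-target values with those ranges.  The package implements the
  printed equations and reports the computed amplitudes.
* The LFP is a current-sum proxy, not a biophysical forward model: no
  electrode geometry, no dipole cancellation.
* No gap junctions, NMDA receptors, synaptic plasticity or
  distance-dependent delays; connectivity is homogeneous Bernoulli.
* Delays snap to the 0.05 ms integration grid, and delayed events beyond
  the trial end are dropped.
* The rate-coding scatter needs `sigma_scale` well above 1 to show the
  drive-tracking correlation, because the printed OU standard deviation
  is negligible against the printed mean rate; the package treats both
  printed values as authoritative and leaves the scaling explicit.
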