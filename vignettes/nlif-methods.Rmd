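---
title: "Reduced integrate-and-fire models of auditory coincidence detectors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced integrate-and-fire models of auditory coincidence detectors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlif)
```

## The scientific problem

Barn owls localise sound azimuth from interaural time differences (ITDs) of
a few microseconds. The neurons that read this cue out — coincidence
detectors of the nucleus laminaris (NL) — receive phase-locked spike trains
from both ears at stimulus frequencies of several kHz and modulate their
firing rate with the relative phase of the two inputs. Biophysically
detailed Hodgkin–Huxley models of these cells reproduce the physiology but
are expensive and hard to analyse. `nlif` implements a family of reduced
conductance-based integrate-and-fire (IF) models of the owl NL neuron,
together with the stochastic binaural input model and the complete battery
of evaluation protocols needed to test them against published
electrophysiology.

## The model family

Four variants share a somatic compartment with capacitance $C_{soma}$, leak
$g_{leak}(E_L - V)$, synaptic current $g_{syn}(t)(E_{syn} - V)$ and, in the
"active" variants, a low-voltage-activated potassium current

$$I_{KLVA} = \bar g_{KLVA}\, d(V, t)\, (E_K - V),$$

whose activation gate relaxes as $\dot d = (d_\infty(V) - d)/\tau_d(V)$ with

$$\alpha_d(V) = 0.20\, e^{(V+60)/21.8},\qquad
  \beta_d(V) = 0.17\, e^{-(V+60)/14} \quad [1/\mathrm{ms}],$$

$d_\infty = \alpha_d/(\alpha_d+\beta_d)$ and
$\tau_d = Q_{10}^{-(T_1-T_0)/10}/(\alpha_d+\beta_d)$
($Q_{10} = 2.5$, $T_0 = 23$ °C slice temperature, $T_1 = 40$ °C body
temperature).

* **Two-compartment active IF** — the soma is coupled through an axial
  conductance $g_{axon}$ to a small node ($C_{node} = 0.2$ pF) that carries
  the spike generator; threshold is monitored on $V_{node}$.
* **One-compartment active IF** — the spike generator acts directly on the
  soma.
* **One-compartment passive IF** — no KLVA; the leak is raised to 240 nS so
  the input resistance is preserved.
* **Non-spiking** — subthreshold soma only (no thresholding unit and no
  generator bias current).

The spike generator injects $I_{IF} = I_{const} + I_{spike}$, where the
stereotyped transient started at each threshold crossing $T_\theta$ is

$$I_{spike}(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} \quad (t \ge 0),$$

standing in for the back-propagating action potential of the remote
initiation site. Detection is disabled for an absolute refractory period
$T_{ref}$ after each crossing. All defaults are the published values
(`nl_model()` reproduces them field by field); the unit system is mV–ms–nS–
pF–pA, in which every current term lands in pA and $I/C$ in mV/ms with no
hidden conversion factors.

Two readings of the published gate equations are physically untenable and
were resolved as follows. Read literally, the relaxation equation has the
sign $\dot d = (d - d_\infty)/\tau_d$, which is unstable; we implement the
standard stable relaxation. Read literally, the $\tau_d$ expression
*multiplies* $1/(\alpha+\beta)$ by $Q_{10}^{(T_1-T_0)/10}$, i.e. the gate
would get slower at body temperature; we divide (a $\approx 4.75\times$
speed-up), the physiological Q10 convention, and expose
`klva_kinetics(q10_convention = "literal")` so the literal reading can be
forced.

A related open point is whether the generator bias $I_{const}$ flows in the
non-spiking variant; its circuit has no thresholding unit at all, so we
exclude it there. Its resting potential is then set purely by the
leak–KLVA balance:

```{r}
resting_potential(nl_model("non_spiking"))
resting_potential(nl_model("one_comp_active_if"))
resting_potential(nl_model("one_comp_passive_if"))  # E_L + I_const/g_leak
```

## Steady states and the small-signal membrane

`steady_state_residual()` evaluates the stationary current balance with
$d = d_\infty(V)$ and the node (if present) eliminated at its own
equilibrium; roots, holding currents, and slope resistances derive from it.
"Membrane resistance" is the *slope* (differential) resistance: only the
linearisation that includes the $\partial d_\infty/\partial V$ term
reproduces the published 4.4 MΩ at −61 mV (the chord resistance gives
≈ 6.8 MΩ), so `input_resistance()` probes with ±10 pA steps and a central
difference:

```{r}
input_resistance(nl_model("one_comp_active_if"), V_hold = -61)
membrane_time_constant(nl_model("one_comp_active_if"), V_hold = -61)
```

`impedance_magnitude()` gives the corresponding small-signal impedance,
with the KLVA branch entering as the usual phenomenological inductive term
$\bar g (V - E_K)\, d_\infty'(V)/(1 + i\omega\tau_d)$ and the node as an
axial load; switching branches off reproduces "RC only", "RC + KLVA" and
"RC + axon" conditions.

## Numerical scheme

Integration is explicit (forward) Euler on the membrane potentials and the
gate, with the synaptic conductance sampled piecewise-constant per step.
The spike-current state is kept as two components $(s_1, s_2)$ decayed by
the exact factors $e^{-\Delta t/\tau_i}$ each step, so the recursive state
equals the closed-form superposition over all past crossings to $10^{-9}$
relative accuracy (a tested invariant). Successive transients superpose
linearly rather than resetting; with $T_{ref} = 0.9$ ms $\gg \tau_1$ and
$\approx 4.5\,\tau_2$, the residual overlap is ~1%.

Threshold events get sub-step treatment, and this choice deserves its
rationale. A plain implementation stamps the crossing at the end of the
Euler step on which threshold is first met and adds $(A_1, A_2)$ whole.
The spike current then starts up to $\Delta t$ late relative to a
fine-step solution of the same inputs. At the initial transient slope
($(A_1+A_2)/C_{soma} \approx 270$ mV/ms for the one-compartment model) a
lag of even 2 µs produces a pointwise discrepancy larger than the 0.5 mV
reliability criterion used below, and the induced shifts in refractory
release flip marginal crossings, so *no* coarse step would ever pass the
criterion. We therefore locate $T_\theta$ within the step by linear
interpolation of the monitored potential, initialise the components with
their exactly decayed values $A_i e^{-(t_{end}-T_\theta)/\tau_i}$, and
deposit the charge the transient would have delivered before the step end,
$\sum_i A_i \tau_i (1 - e^{-(t_{end}-T_\theta)/\tau_i})$, on the
spike-generating compartment as a voltage impulse. The injected waveform is
then charge-conserving and timed from the crossing itself, making spike
times and post-spike trajectories nearly independent of $\Delta t$.
Refractory release is continuous: if the potential still exceeds threshold
when $T_{ref}$ elapses, the next crossing is stamped at exactly
$T_{last} + T_{ref}$. During the refractory period only detection is
disabled; membrane dynamics, $I_{const}$, and the decaying transients run
on unaltered.

Other numerical conventions: simulations start with $d = d_\infty(V_0)$,
$s_1 = s_2 = 0$, and the node at its conditional steady state given
$V_{soma} = V_0$ (resting potential unless a holding protocol specifies
otherwise); the gate is clamped to $[0,1]$ and the run flagged if clamping
ever triggers (it never does under default drive at $\Delta t \le 15$ µs);
a non-finite state raises an error unless `allow_divergence = TRUE`, which
the reliability protocol uses because the two-compartment node
($\tau_{node} = C_{node}/(g_{leak}^{node}+g_{axon}) \approx 1.7$ µs) makes
forward Euler genuinely unstable for $\Delta t \gtrsim 3.3$ µs. The plain-R
`euler_step()` mirrors the compiled loop step for step and is held equal to
it by tests.

## Synaptic input model

Each side contributes $M = 150$ independent fibers firing as inhomogeneous
Poisson processes, phase-locked to $f_{stim} = 4000$ Hz with vector
strength $r = 0.6$ at mean rate $\lambda_0 = 500$ spikes/s. The published
description defers the exact intensity function to earlier work, so the
generator uses the canonical circular-statistics choice, a von Mises
profile

$$\lambda(t) = \lambda_0\, e^{\kappa \cos(2\pi f_{stim} t)} / I_0(\kappa),
  \qquad I_1(\kappa)/I_0(\kappa) = r,$$

realised by thinning a homogeneous process at the intensity maximum. The
mean rate is exactly $\lambda_0$ and the vector strength of generated
trains converges to $r$ (both tested); any intensity with vector strength
$r$ has the same first Fourier component $2r\lambda_0$, so the choice of
profile affects only higher harmonics. All fibers of one side lock to
phase zero.

Each presynaptic spike injects a unitary alpha conductance
$\alpha(t) = H_\alpha (t/\tau_\alpha) e^{1-t/\tau_\alpha}$ with
$H_\alpha = 1.3$ nS and half-width $W_\alpha = 2.446\,\tau_\alpha =
0.1$ ms, truncated $10\,\tau_\alpha$ after onset (residual
$< 3\times10^{-4}$ of peak). The interaural phase difference $\delta$
shifts the contralateral trace by $\delta/2\pi f_{stim}$, rounded to the
nearest grid step and wrapped circularly so rate–phase curves are
stationary in $\delta$; a 20-ms warm-up is excluded from all rate counts.
One drawn realisation serves every $\delta$ and every grid point of a
parameter sweep (common random numbers), which makes rate *differences*
across a sweep far less noisy than the individual rates.

What the generator does **not** emulate: synaptic depression or
facilitation, conduction-delay jitter, frequency dependence of vector
strength, or non-stationary sound envelopes. Passing tests therefore show
that the models behave correctly under stationary, statistically ideal
drive — not that they reproduce every property of in vivo input.

## Evaluation protocols

* **Step-current classification** (`classify_step_response()`): the model
  is held at −60 mV by a computed bias current, settled for 20 ms, and
  stepped for 50 ms. The published definitions are verbal, so the
  operational rule is: *no-spike* if the step window contains no spike;
  *phasic* if there is exactly one spike or all spikes fall within a 5-ms
  onset window (a configurable knob); *tonic* otherwise. Classification of
  the active models' phasic band is stable for step durations ≥ 50 ms.
* **Spike shape** (`average_spike_shape()`): 300 non-phase-locked Poisson
  fibers at 500 Hz drive the model until 1500 output spikes are collected;
  windows of [−1, +2] ms around each threshold-crossing sample are
  averaged. Amplitude is peak minus the pre-spike baseline (mean over
  [−1.0, −0.5] ms); because the baseline convention is not unique, the
  peak-minus-threshold amplitude is reported alongside. Width is measured
  at half amplitude with linear interpolation. The waveform-measurement
  step is $\Delta t = 2$ µs in the reproduction script — well below the
  scheme's reliability bound, where the averaged waveform has converged
  (at 10 µs the Euler overshoot inflates the peak by ~0.6 mV).
* **Rate–phase curves** (`rate_phase_curve()`): spike rates over a grid of
  $\delta$, 10 s of simulated time per point at $\Delta t = 10$ µs
  (single-compartment models; 1 µs for the two-compartment model, which is
  unstable at 10 µs). In-phase and out-of-phase rates are read at the grid
  points nearest $\{0, \pm 2\pi\}$ and $\{\pm\pi\}$; counting-noise
  standard errors $\sqrt{N}/T$ accompany every rate.
* **Robustness sweeps** (`sweep_threshold()`, `sweep_refractory()`):
  thresholds over a 5-mV window at 0.2-mV spacing (10 s per point, common
  random numbers), refractory periods on (0, 1.6] ms. The threshold sweep
  reports the width of the longest contiguous interval with modulation
  depth above 180 spikes/s, edges interpolated linearly between grid
  points.
* **Time-step reliability** (`reliability_max_dt()`): presynaptic event
  times are drawn once; for each candidate $\Delta t$ the conductance is
  re-sampled from those events and the somatic trace compared with a
  0.1-µs reference at the coarse grid's time points; a step is unreliable
  if the maximum deviation exceeds 0.5 mV over the traces (three 1-s
  realisations by default; ten for the two-compartment model in the
  reproduction script, whose 3-µs verdict sits close to the criterion).

## The reliability measure, and a known limitation

With each run doing its own threshold detection (`mode = "pointwise"`),
the maximum deviation between a coarse and a fine run is dominated by
*crossing flips*: a marginal subthreshold peak that crosses in one run and
not the other produces a spike-sized (~9 mV) excursion lasting an
interspike interval. Measured flip rates grow roughly linearly with
$\Delta t$ (about 10 unmatched spikes per second already at 1 µs), so on
1-s spiking traces no tested step ever passes the 0.5-mV criterion — the
metric measures trajectory chaos, not integration quality. The default
`mode = "matched"` therefore replays the reference run's spike sequence in
every candidate run, isolating what the criterion is meant to measure:
subthreshold accuracy, spike-waveform accuracy, and instability of the
spike-generating compartment.

Under this measure the two-compartment model is unreliable from 3 µs
upward (the node's Euler ringing) with a maximum allowable step of 2 µs,
matching the published verdict. For the single-compartment models the
measured boundary is 3–5 µs, *not* the published ~15 µs: the residual at
15 µs (~1.7 mV) is intrinsic forward-Euler error — a ~0.5 mV subthreshold
phase lag of the 4-kHz-driven membrane plus spike-peak error — which any
forward-Euler implementation of these equations shares. We could not find
a pointwise-maximum reading of the criterion that includes spike windows
and yields 15 µs; the package reports what its own measure produces rather
than tuning the metric per model.

## The passive model under default drive

A second systematic deviation from the published account is documented
here rather than hidden. The binaural drive has mean conductance
$2 M \lambda_0 H_\alpha e \tau_\alpha \approx 21.7$ nS, which for the
passive variant (no $E_K$ drag) puts the mean somatic potential near
−54.3 mV — about 4.3 mV *above* its default threshold of −58.6 mV, far
exceeding the ~1 mV stimulus-frequency oscillation. The passive model
consequently fires at the refractory ceiling $1000/T_{ref}$ for every
phase: its in-phase rate (1111 spikes/s at 0.9 ms) exceeds the typical
discharge range, as published, but its modulation depth is ~0 around the
default threshold, and the refractory effect 0.8 → 1.6 ms is the
cap-to-cap difference 625 spikes/s rather than the published 310. The
modulation band actually sits at thresholds of about −53.7 to −51.9 mV
(width ≈ 1.8 mV), just above the mean drive. The active models — whose
KLVA current holds the mean potential below threshold — reproduce the
published rates, refractory effects and robustness widths, so the drive
normalisation itself is validated; reconciling the passive model appears
to require a different balance of mean versus modulated drive than the
printed synaptic parameters produce.

## Problem sizes and runtime choices

The test-suite and reproduction runs use: 10 s of simulated time per rate
estimate (standard error ≈ 7 spikes/s at 500 spikes/s), 1500 spikes per
waveform, three (one-compartment) or ten (two-compartment) 1-s traces per
reliability comparison, and 26-point threshold grids. The compiled core
advances roughly $3\times10^7$ states per second, so the full reproduction
completes in a few minutes.
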