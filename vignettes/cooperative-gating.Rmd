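---
title: "Cooperative sodium-channel gating: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative sodium-channel gating: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopna)
```

## The scientific question

Conductance-based neuron models almost always assume that voltage-gated
sodium channels gate independently, coupled only through the membrane
potential.  Clustered channels, however, can gate cooperatively: the
opening of one channel raises the open probability of its neighbours.
`coopna` implements a model class built around this idea and asks three
questions with it:

1. What does cooperativity do to the *activation curve* of a channel
   population under voltage clamp?
2. What does a *fraction* of cooperative channels do to the action
   potential (AP) of a conductance-based neuron — its onset rapidness,
   threshold statistics, and waveform?
3. Does it change what a *population* of such neurons can encode,
   specifically its sensitivity to fast input fluctuations?

## Mean-field kinetics of a coupled channel population

Each channel is coupled to $K$ neighbours; each open neighbour shifts its
activation curve by $J$ mV (operationally, a shift along the voltage axis
that has the same effect on open probability as the neighbour's opening).
With single-channel Boltzmann activation
$m_\infty(V) = \bigl(1 + e^{-(V - V_{1/2})/k}\bigr)^{-1}$,
activation exponent $q$ (open probability $m^q$), available — i.e. not
inactivated — fraction $a$, and effective coupling $\mu = KJ$, the
mean-field kinetics of the activation variable are
$$
\tau_m \frac{dm}{dt} = m_\infty\!\bigl(V + \mu\, a\, m^q\bigr) - m .
$$
The argument shift $\mu a m^q$ is the expected open fraction among an
available channel's neighbours times the per-neighbour shift.  At
$\mu = 0$ the population reduces exactly to independent channels; every
operation in the package preserves this limit.

At clamped voltage the steady states are fixed points of the monotone
self-consistency map $F(m) = m_\infty(V + \mu a m^q)$
(`self_consistency_map()`, `fixed_points()`).  For weak coupling the map
has one fixed point; beyond a critical coupling $\mu_c$ three appear over
a window of voltages, the outer two stable.  Where the lower stable branch
collides with the unstable branch (a saddle-node/tangency), the
steady-state open fraction jumps: the *collective activation curve*
becomes discontinuous and activation of the population is all-or-none.
For $q = 1$ the tangency condition $m(1-m) = k/(\mu a)$ gives the closed
forms implemented in `critical_coupling()` and `threshold_voltage()`:
$$
\mu_c = \frac{4k}{a}, \qquad
m_{sn} = \frac{1 - \sqrt{1 - 4k/(\mu a)}}{2}, \qquad
V^* = V_{1/2} + k \ln\frac{m_{sn}}{1 - m_{sn}} - \mu a\, m_{sn}.
$$
For $q \neq 1$ both quantities are found numerically from the
monotonicity of the fixed-point voltage curve
$v(m) = V_{1/2} + k\,\mathrm{logit}(m) - \mu a m^q$; this criterion is
equivalent to the existence of three fixed points but does not require
resolving the (arbitrarily narrow) near-critical bistable voltage window,
which a naive root-counting scan cannot do at the advertised $10^{-4}$
relative tolerance.

In the strong-coupling limit $V^* \approx \text{const} - k\ln(\mu a)$, so
the sensitivity of the jump voltage to the available fraction,
$dV^*/d\ln a$ (`threshold_sensitivity()`), approaches $-k$ independently
of the coupling.  This is the analytic backbone of the threshold-variability
results below: inactivation moves the spike threshold, and coupling
strength does not suppress that motion.

### Voltage-clamp protocol and branch convention

`collective_activation_curve()` emulates the experimental protocol of
voltage steps of increasing amplitude applied from a common holding
state: the steady state at each grid voltage is obtained by relaxing from
the steady state of the previous one (ascending continuation; the
"forward" branch).  The backward branch, provided for hysteresis
analysis, jumps at a lower voltage; the two coincide outside the bistable
window.  Jumps are flagged when adjacent open fractions differ by more
than 0.2 — far above the slope of any continuous sub-critical curve on
the default 0.1 mV grid — and the jump voltage is then refined by
bisection to 0.01 mV.  Near-tangent (double) fixed-point roots are
recovered by polishing grid minima of $|F(m) - m|$, so saddle-node points
are not lost between sign changes.

Relaxation to steady state uses iteration of the map $F$ itself: for a
continuous increasing self-map of $[0,1]$ the iteration is monotone from
any starting point and converges to the stable fixed point on the branch
containing the start, which is exactly the attractor of the relaxation
ODE.  Just above a saddle-node the ODE (and `simulate_gate_step()`) slows
critically through the ghost; tests therefore probe steady-state equality
away from the jump voltage.

## The cooperative Wang-Buzsaki neuron

The neuron (`cwb_params()`, `integrate_cwb()`) is the Wang-Buzsaki (WB)
fast-spiking interneuron model with the sodium conductance split: a
fraction $1-p$ keeps the standard WB channel (instantaneous activation
$m_\infty(V)^3$, inactivation $h$), a fraction $p$ gates cooperatively:
$$
C \dot V = -g_{Na}\bigl[(1-p)\,m_\infty(V)^3 h + p\, m_c^q h_c\bigr](V - E_{Na})
           - g_K n^4 (V - E_K) - g_L (V - E_L) + I(t).
$$
$m_c$ follows the mean-field kinetics above with the *live* available
fraction $a = h_c$ (in the voltage-clamp module $a$ is frozen, matching
the clamp protocol where inactivation is held constant).  Inactivation of
the cooperative fraction is channel-state dependent — open channels
inactivate fast at any voltage — implemented as the WB closing rate
multiplied by $(1 + \kappa m_c^q)$:
$$
\dot h_c = \phi\bigl[\alpha_h(V)(1 - h_c)
            - \beta_h(V)\,(1 + \kappa m_c^q)\, h_c\bigr].
$$
Inactivation itself remains independent and first-order; only its rate
responds to the open fraction.  $\kappa = 0$ recovers purely
voltage-dependent WB inactivation, and $p = 0$ recovers the plain WB
model exactly (asserted against an independently coded WB simulator in
the tests).

### Default parameters and why

WB membrane parameters are the standard published ones
($C = 1\,\mu F/cm^2$, $g_{Na} = 35$, $g_K = 9$, $g_L = 0.1\,mS/cm^2$,
$E_{Na} = 55$, $E_K = -90$, $E_L = -65$ mV, $\phi = 5$).  The cooperative
gate of the neuron defaults to a low-threshold, delayed-activation
Boltzmann gate:

| parameter | default | meaning |
|---|---|---|
| $V_{1/2}$ | $-50$ mV | midpoint of the single-channel Boltzmann |
| $k$ | 4 mV | slope factor |
| $q$ | 3 | activation exponent (delayed activation) |
| $\tau_m$ | 0.05 ms | activation time constant |
| $K$ | 6 | coupled neighbours |
| $\kappa$ | 25 | open-state inactivation gain |

These defaults are a reconstruction, chosen once by forward reasoning
about the phenomenology the model class is meant to display, and exposed
as configuration:

* **$q = 3$ (delayed activation).**  With $q = 1$ any Boltzmann gate
  placed low enough to matter during AP initiation carries a resting open
  probability of order $10^{-2}$–$10^{-3}$; at $p \gtrsim 0.02$ the
  resulting persistent sodium current exceeds the WB rheobase and the
  cell loses its resting state entirely.  Cubing the gate suppresses the
  resting tail by orders of magnitude while leaving the collective jump
  intact, and is the variant the delayed-activation sodium literature
  supports.  The voltage-clamp module keeps $q = 1$ defaults
  ($V_{1/2} = -30$, $k = 6$ mV), where the closed-form analysis lives.
* **$V_{1/2} = -50$, $k = 4$ mV.**  Places the collective jump voltage
  $V^*$ a few millivolts *below* the activation range of the
  non-cooperative WB current once $\mu$ exceeds a few multiples of
  $\mu_c$ ($V^* \approx -55$ to $-59$ mV for $\mu = 72$–$576$ mV at the
  resting $h_c$).  The cooperative fraction then opens first and triggers
  the AP — the low-threshold, axon-initial-segment-like population the
  cooperative fraction is meant to represent.
* **$\tau_m = 0.05$ ms** keeps the collective opening fast on the scale
  of the AP upstroke; the default integrator step (RK4, $dt = 0.01$ ms)
  resolves it with $\tau_m / dt = 5$, and all onset metrics are verified
  stable under $dt$ halving.
* **$\kappa = 25$.**  The inactivation gain controls how transient the
  cooperative surge is, and thereby the waveform class.  The upstroke
  dwell time in the inter-phase voltage range scales like $1/(p\,g_{Na})$
  while the inactivation rate is fixed, so a fast open-state inactivation
  truncates the cooperative phase only when the fraction is small: APs
  are biphasic (two acceleration phases, three zero crossings of
  $\ddot V$) for small $p$ and strong $\mu$, and monophasic for large $p$
  or weak coupling, with peak $dV/dt$ still growing with both $p$ and
  $\mu$ in the small-fraction regime ($p \le 0.1$) that is this package's
  study domain.  Substantially smaller $\kappa$ never interrupts the
  surge (no biphasic regime); substantially larger $\kappa$ truncates it
  at every $p$.
* **Beyond the small-fraction regime** ($p \gtrsim 0.2$) state-dependent
  inactivation consumes an increasing share of the sodium current during
  the upstroke, so peak $dV/dt$ is no longer monotone in $p$ and at
  $p \to 1$ the model degenerates (strongly truncated, low-amplitude
  spikes).  This is a known limitation of the reconstruction, not a
  property claimed for the model class.

### Integration and numerical choices

Fixed-step classical Runge-Kutta (RK4) with the stimulus held constant
over each step, compiled in C++; $dt = 0.01$ ms by default.  Gating
variables are clipped to $[0,1]$ after each step and clip events counted
(zero in every protocol used by the tests).  Deterministic given
parameters, stimulus and step; a non-finite state aborts with the failure
time.  Spike times are upward level crossings (0 mV) with linear
interpolation and a 2 ms refractory constraint.

Phase-plane quantities take $dV/dt$ from the model right-hand side
evaluated along the stored states rather than differencing the sampled
voltage, eliminating differentiation noise from the zero-crossing count;
a finite-difference mode remains available for externally recorded
traces.  The AP threshold is the voltage at the first upward crossing of
$dV/dt = 10$ mV/ms (configurable criterion); onset rapidness is the
least-squares phase-plot slope over the arc with $dV/dt$ within
criterion $\pm$ criterion/2; the upstroke window for waveform
classification runs from the criterion crossing to the voltage peak, and
sign lobes of $\ddot V$ smaller than 1% of the window maximum are
ignored as numerical ripple.

### Threshold variability under fluctuating input

Under OU input the per-spike threshold of the plain WB neuron varies with
the gating state at initiation; making the activation effectively steeper
(increasing $\mu$) reduces that variability while increasing onset
rapidness — the classic antagonism.  Under strong coupling initiation
happens at the collective jump, whose voltage moves with the available
fraction at sensitivity $\approx -k/2\ldots-k$ per e-fold; spike-to-spike
variation of $h_c$ then sets the threshold variability, and both
rapidness and variability grow with $\mu$.  In this reconstruction the
antagonistic branch persists somewhat beyond $\mu_c$ (threshold sd keeps
falling until roughly $15\,\mu_c$, where residual crossing jitter still
dominates) and the inactivation-driven positive branch appears under
strong coupling ($\mu = 240$–$720$ mV at $p = 0.1$, OU $\sigma = 1\,
\mu A/cm^2$, $\tau_c = 20$ ms, ~45 Hz firing); the tests assert the
negative correlation across sub-critical couplings and the positive
correlation across that strong-coupling range.

## Population encoding

Encoding is measured as the modulation $\nu_1(f)$ of the population
firing rate by a weak sinusoidal current embedded in OU background
noise, $I(t) = i_0 + i_1 \sin(2\pi f t) + \eta(t)$.  The OU process uses
the exact discretization (stationary for any step), the baseline $i_0$ is
calibrated by bisection to a target mean rate, and $\nu_1$ and its phase
are the Fourier projection of the pooled spike times at the stimulus
frequency,
$\nu_1 e^{i\varphi} = (2/T)\sum_j e^{-2\pi i f t_j}$ — the fundamental of
the cycle histogram without binning bias (the estimator choice is ours;
standard alternatives agree at the fundamental).  Standard errors come
from a 200-resample bootstrap over trials; trials are statistically
independent neurons with a 200 ms discarded transient.

Defaults: target rate 5 Hz, OU $\sigma = 0.3\,\mu A/cm^2$ (≈ 3.8 mV
voltage SD at rest), $\tau_c = 20$ ms, $i_1 = 0.3\,\mu A/cm^2$.  The
quantity of interest is the *ordering* at high frequency (≈ 100 Hz) at
matched mean rate: the cooperative model's $\nu_1$ exceeds the plain WB
value severalfold, a ten-fold sodium-density increase does not help, and
the ordering survives slower background noise ($\tau_c$ 20–60 ms).
Absolute gain values depend on every protocol constant and are not
asserted.

## What the synthetic fixtures emulate

The test surface uses generators with known ground truth
(`make_fixtures()`): logistic and double-logistic upstrokes whose second
derivative has exactly one and three sign changes; exponential-rise
segments whose phase plot is exactly a line (threshold and slope in
closed form); and inhomogeneous-Poisson spike trains with rate
$\nu_0 + \nu_1\sin(2\pi f t)$ by thinning, for the modulation estimator.
They validate the *analysis* operations independently of the simulator.
What they do not emulate: real measurement noise, electrode filtering,
channel stochasticity, or morphology — passing tests say the analysis is
correct on its stated model class, not that the model captures every
property of cortical recordings.

## Problem sizes

The shipped tests and the acceptance script run desk-scale protocols
chosen to keep the whole suite in the low minutes on one core: 300–600 ms
step-current simulations at $dt = 0.005$–0.01 ms for waveform metrics, a
4×4 $(p, \mu)$ sweep, 10 s OU trajectories per coupling for threshold
statistics, and 12–20 trials × 2.2 s per frequency for encoding.  All
protocol constants are function arguments, so larger runs are a
configuration change, not a code change.

## Known limitations

* All cooperative-gate parameter values are reconstructions (the model
  class, not a fitted cell); conclusions are orderings and bifurcation
  structure, not absolute numbers.
* The mean-field approximation ignores channel-number fluctuations;
  there is no stochastic single-channel simulation.
* Single compartment only: no morphology, no lateral axonal currents,
  which are the competing explanation for rapid somatic AP onsets.
* Inactivation of the cooperative fraction beyond the state-dependent
  rate speed-up (e.g. slow inactivation) is not modelled; the
  large-$p$ degeneracy discussed above follows from this.
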