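# coopna

Cooperative sodium-channel gating in conductance-based neuron models.

Voltage-gated sodium channels are almost always modelled as gating
independently, coupled only through the membrane potential.  Clustered
channels, however, can gate *cooperatively*: one channel's opening raises
its neighbours' open probability.  `coopna` is for computational
neuroscientists who want to study what that does to action-potential (AP)
initiation and to population coding.  It provides, end to end:

* **Mean-field kinetics of a coupled channel population** — each channel
  coupled to *K* neighbours, each open neighbour shifting the Boltzmann
  activation curve by *J* mV.  With effective coupling μ = *K·J*,
  available fraction *a* and activation exponent *q*, the activation
  variable obeys τₘ dm/dt = m∞(V + μ a mᑫ) − m.  The package computes the
  fixed points of the self-consistency map F(m) = m∞(V + μ a mᑫ), the
  collective activation curve with its hysteresis branches, the critical
  coupling μ_c at which the curve develops a discontinuity (μ_c = 4k/a
  for q = 1), the jump voltage V* = V₁,₂ + k·ln(m_sn/(1−m_sn)) − μ a m_sn
  at the saddle-node m_sn, and the sensitivity dV*/d ln a → −k that makes
  inactivation-driven threshold variability coupling-independent.
* **The cooperative Wang-Buzsaki (cWB) neuron** — the WB interneuron
  model with a fraction *p* of its sodium conductance gating
  cooperatively, with open-state-dependent inactivation of that fraction
  (closing rate × (1 + κ m_cᑫ)).  Compiled fixed-step RK4 integrator,
  spike detection, f-I curves; p = 0 reduces exactly to plain WB.
* **AP phase-plane metrics** — threshold at a dV/dt criterion, onset
  rapidness (phase-plot slope), peak dV/dt, and monophasic/biphasic
  classification by counting zero crossings of the second derivative
  during the upstroke, plus (p, μ) parameter sweeps.
* **Population frequency response** — Ornstein-Uhlenbeck background
  noise, baseline-current calibration to a target rate, and the
  firing-rate modulation ν₁(f) by Fourier projection of pooled spike
  times, with bootstrap errors.

## Worked example

```r
library(coopna)

## 1. Voltage-clamp: the collective activation curve develops a jump
gate <- coop_gate_params()          # Boltzmann: v_half -30 mV, k 6 mV, q 1
critical_coupling(a = 1, gate)
#> [1] 24
threshold_voltage(mu = 48, a = 1, gate)
#> [1] -47.60592
curve <- collective_activation_curve(set_coop_mu(gate, 48), a = 1,
                                     v_grid = seq(-70, 0, 0.1))
curve
#> Collective activation curve (forward branch, a = 1, mu = 48 mV)
#>   discontinuous: jump of 0.872 at V* = -47.60 mV

## 2. A small fraction of strongly coupled channels reshapes the AP
neuron <- cwb_params(p = 0.1)                  # 10% cooperative channels
neuron$coop <- set_coop_mu(neuron$coop, 144)   # ~9x critical coupling
traj <- integrate_cwb(neuron, stimulus = 0.2, t_end = 600)  # uA/cm2, ms
spikes <- detect_spikes(traj)
seg <- extract_spike_segments(traj, spikes[spikes > 200])
ap_metrics(seg[[length(seg)]])
#>   threshold_mV rapidness_per_ms peak_vdot waveform_class zero_crossings
#> 1    -54.36078         9.972159  640.3771       biphasic              3
```

At twice the critical coupling the channel population's steady-state open
fraction jumps by 0.87 at −47.6 mV — activation has become an all-or-none
event, and the jump voltage matches the tangency closed form.  In the
neuron, 10% cooperative channels drop the spike threshold to −54.4 mV,
quadruple the onset rapidness relative to plain WB (≈ 2.4/ms under the
same protocol), and make the upstroke biphasic: the acceleration shows
two phases (cooperative fraction first, remaining channels second), i.e.
three zero crossings of d²V/dt², where the plain WB model shows one.

A command-line interface wraps the same pipelines
(`simulate`, `activation-curve`, `ap-metrics`, `sweep`, `freq-response`,
`fixtures`), driven by JSON/YAML configs with a `--seed` flag; every
output directory receives the fully resolved config for bit-exact reruns.

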