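---
title: "chipause: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chipause: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipause)
```

## The scientific question

Striatal cholinergic interneurons (ChIs) are tonically active (3–10 Hz) and
show stereotyped *pauses*, often flanked by *rebounds*, in response to
salient stimuli. `chipause` implements and stress-tests a mechanistic
hypothesis: ChIs behave as **differentiators of their excitatory input**.
Their firing tracks the *rate of change* of net excitation, and the pause is
the signature of *receding* input, mediated by a slow, non-inactivating
delayed-rectifier K⁺ current (I_Kr, Kv7-like). When depolarizing input rises,
the slowly activating I_Kr lags behind and the membrane overshoots; when the
input recedes, the still-activated I_Kr outlasts it and drags the membrane
*below* rest — the undershoot that interrupts tonic firing. A
hyperpolarization-activated current (I_h) is not modelled explicitly: its
depolarizing influence is absorbed into the resting-potential setting, and
"blocking" it is emulated by recalibrating rest to −76 mV, where the
voltage range of dynamic I_Kr activation is no longer visited.

## The model

A single cylindrical compartment (diameter 15 μm, length 40 μm, lateral area
π·d·L ≈ 1.885·10⁻⁵ cm², C_m = 1 μF/cm², 33 °C metadata) with:

* passive leak: g_leak = 0.09 mS/cm², reversal E_leak calibrated (below);
* I_A: ḡ = 2 mS/cm², E_K = −85 mV, fast activation
  (V½ = −40 mV, k = 15 mV, τ = 2 ms) and inactivation
  (V½ = −70 mV, k = −7 mV, τ = 15 ms);
* I_Kr: ḡ = 0.5 mS/cm², E_K = −85 mV, non-inactivating, activation
  V½ = −30 mV, k = 3 mV, with a Gaussian-bell time constant
  τ(V) = 50 + 350·exp(−((V+40)/15)²) ms (≈400 ms near rest, ≈50 ms when
  hyperpolarized).

Gates follow x∞(V) = 1/(1+exp(−(V−V½)/k)), dx/dt = (x∞−x)/τ(V), exponent 1.
Sign conventions, used consistently everywhere: outward membrane current is
positive; depolarizing injected current is positive. Somatic currents (pA)
become densities (μA/cm²) via the membrane area.

### Where the kinetic numbers come from

Geometry, capacitance, leak conductance, maximal conductances, reversal
potentials and the two resting-potential targets are fixed by the
experimental compartment description this model reimplements. The gate
kinetics are not part of that description — experimentally they come from
earlier ChI voltage-clamp work — so here they are configuration
(`inst/extdata/default_model.json`), with defaults chosen once to satisfy
the qualitative constraints the benchmark scenarios impose: I_Kr slow
(τ of order 10²–4·10² ms, so its current lags ramping input),
non-inactivating, activating between −60 and −30 mV; I_A fast (τ ≤ 15 ms)
and inactivating. Two consequences deserve honesty:

* **The steep I_Kr slope (3 mV).** The prescribed leak (0.09 mS/cm²) is
  small and the prescribed ḡ_Kr (0.5 mS/cm²) is large; for the cell to rest at
  −40 mV with the leak reversal inside a plausible (−120, 0) mV range, the
  I_Kr open fraction at −40 mV must stay small, forcing either a depolarized
  half-activation or a steep slope. Experimental Kv7 slopes are shallower
  (~9–12 mV); the steep default trades that realism for the prescribed
  resting state and undershoot behaviour. With it the model's undershoots
  (e.g. ~8–22 mV across 25–100 pA half-sine inputs) are several-fold larger
  than the ~2.7 mV measured in real ChIs at 50 pA — the *qualitative*
  claims (I_Kr-dependence, scaling, voltage-dependence) are what the test
  suite asserts.
* **The τ(V) bell.** τ peaks at rest (−40 mV) and falls to 50 ms when
  hyperpolarized. The fast hyperpolarized τ keeps the post-input trough
  latency nearly amplitude-invariant (range < 20 ms across 25–100 pA),
  which wide bells or constant τ do not achieve in this strongly
  rectifying configuration.

### Setting the resting potential

The experiment "sets" rest without saying how. Decision: solve the zero-input
steady-state balance g_leak(V_t − E_leak) + ΣI_c(V_t) = I_hold for E_leak —
exact in closed form because the leak is linear in its reversal (a bisection
would only approximate the same root) — then *verify* with a 2 s settling
simulation (must land within 0.1 mV). Solutions outside (−120, 0) mV are
errors. The alternative mechanism, a bias current, is used where the
experiment used it: the "I_h blocked, RMP restored" scenario calibrates the
leak at −76 mV and then re-depolarizes with a constant holding current. For
the I_h-block scenario the −76 mV value is the default (reported values for
this manipulation range to −80 mV; the config exposes it).

### Numerics

Fixed-step exponential Euler for gates, forward Euler for voltage,
dt = 0.025 ms, compiled in C++. Gates initialize at steady state for the
initial voltage (no onset transients). Divergence guard at |V| > 500 mV
errors with the failure time. Halving dt changes the benchmark scenario
traces by < 10⁻⁴ mV in practice (the acceptance bound is 0.1 mV); the
leak-only step response matches the RC closed form to well under 1%.
Voltage-clamp families bypass the ODE solver entirely: at clamped voltage
each gate relaxes in closed form, so steady currents equal
ḡ·x∞^p·(V−E) analytically.

## Stimulus protocols

Sine (25/50/75/100 pA, 500 ms), trapezoid (4 s phases), D₂-receptor current
(quarter-sine rise to a hyperpolarizing peak after an onset latency; linear
or exponential decay), composition of shifted/scaled parts, and the
−13.6 pA undershoot-mimicking current (Ohm's law: 2.72 mV across 200 MΩ).

Two protocol decisions are worth flagging:

* **Half-sine for the amplitude series.** A full 2 Hz cycle ends on its
  *hyperpolarizing* lobe, so the post-input minimum would be input-driven
  (~10 mV at 200 MΩ for 50 pA), incompatible with the ~2.7 mV
  K⁺-current-driven hyperpolarization the protocol is meant to isolate.
  The amplitude-series scenario therefore uses a single depolarizing lobe
  spanning the 500 ms duration; the full-wave builder remains the default
  primitive.
* **D₂ defaults.** Peak −20 pA, onset latency 100 ms, 150 ms rise, 250 ms
  decay (linear), all overridable — the underlying measurements are from
  optogenetic work on dopamine-evoked D₂ currents in ChIs, and only their
  rough scale is constrained here. Scenario timings (catalog data) stretch the decay where a
  protocol needs the D₂ tail to overlap a later epoch.

## Pause/rebound quantification

Rate histograms use 20 ms bins; the baseline is the mean rate over bins
ending ≥ 100 ms before the alignment event (configurable). After normalizing
to baseline = 100%, a centered three-bin moving average is taken (shrinking
windows at the edges); pause amplitude is its minimum, rebound amplitude its
maximum, and onset/end are the nearest 100%-crossings bracketing each
extremum, at bin resolution, flagged `NA` when no crossing exists. Ties
(exactly 100%) break toward the extremum. One deliberate correction: a
centered three-bin average smears each boundary of a step-like change one
bin outward, so reported crossings are pulled back one bin toward the
extremum — with this, a rectangular three-bin dip is recovered at its exact
amplitude and duration.

**What a green recovery test establishes.** On *binned ground-truth
profiles* (the `bin_profile` path) the estimator recovers depth within ±5
percentage points and duration within ±1 bin across randomized scenarios —
that validates binning, smoothing and crossing logic. On *sampled spike
trains* it cannot do that well, at any sweep count: the crossing threshold
sits exactly at the baseline's mean, so adjacent baseline bins fall below
100% with probability ≈ ½ and extend the measured pause stochastically
(at 200 sweeps: duration biased ≈ +80 ms, depth ≈ +8 points from the
minimum statistic's noise). The spike-level test therefore asserts only
tolerances the noise model supports, and real-data durations from this
method should be read with the same caution.

Membrane undershoot statistics (trough below rest after input offset, peak
above rest during input, trough:peak ratio, trough latency from offset) are
computed on spike-free traces. Phase relations use a first-harmonic
projection at the slow frequency rather than cross-correlation peaks —
robust at 20 ms resolution; positive lag means the second profile is
delayed. Unit classification applies the extracellular criteria: broad
(> 1.1 ms) tonic units with minimum ISI > 20 ms are pChIs; broad slow
(< 1 Hz) units are SPNs; narrow units are FSIs; tonic units with minimum
ISI < 10 ms are LTS interneurons.

## Synthetic in-vivo recordings

The generator states a world, not a fit: a 1 Hz sinusoidal inverted-LFP
(amplitude 1 a.u., additive white noise SD 0.1), smoothed with a zero-phase
201 ms running mean and differentiated (circularly, on an endpoint-free
grid) to give the normalized modulation; pChI rate =
baseline·(1 + depth·mod) with baseline 6 Hz and depth 0.8, floored at zero;
the SPN profile is the same modulation delayed by 60° of the slow cycle at
baseline 2 Hz. Spikes are inhomogeneous Poisson (thinning) with an absolute
refractory period (20 ms, matching the pChI minimum-ISI criterion by
construction), 100 sweeps of 16 s by default, all randomness flowing from
one integer seed. Choices that were genuinely open, fixed once:

* *Sweep length 16 s*: in-vivo slow-wave epochs run minutes; 16 cycles give
  the first-harmonic phase estimate a standard error ≈ 2–3°, commensurate
  with the ±5° recovery band. (4 s sweeps leave SE ≈ 5°.)
* *201 ms smoother*: with a 51 ms window, 1 kHz noise leaks into the
  derivative and inflates the max-|d| normalization, shrinking the
  effective modulation depth and the phase signal-to-noise.
* The noise model is the minimal one supporting the analysis layer; it has
  no bursting, no non-stationarity, no LFP harmonics, no electrode
  artifacts — a green phase-recovery test says the estimator works under
  Poisson-with-refractoriness variability, nothing more.

The derivative coupling places the pChI rate maximum a quarter-cycle before
the iLFP maximum (ascending phase) and the minimum on the receding phase at
the descending mean-crossing; with any low-pass in the coupling the minimum
moves slightly earlier, i.e. while the iLFP still exceeds its mean.

## Scenario catalog and known limitations

Scenarios are data (`inst/extdata/scenarios.json`): voltage-step families,
the trapezoid channel-set comparison, ramp lag, resting-potential
comparison, the sine amplitude series, D₂ combinations and timing, learning
scaling, the undershoot mimic, the small-withdrawal check and the in-vivo
phase loop. Thresholds for `report()` live beside them.

One model behaviour required care: a hyperpolarizing D₂ current arriving
*before* rebound input deactivates I_Kr (τ ≈ 400 ms near rest) and can
paradoxically *increase* the rebound peak — hyperpolarization disinhibits.
The D₂-timing scenario therefore places the D₂ current (the slow
GIRK-mediated consequence of a dopamine burst at the pause) so that it
overlaps the rebound window itself; there it suppresses the rebound while
leaving the trough unchanged, as observed. In a model with shallower I_Kr
activation this sensitivity would be weaker; it is a direct consequence of
the steep slope discussed above.

Other limitations: no Na⁺/Ca²⁺ spikes (tonic firing is not simulated;
"TTX-like" subthreshold analysis is the native regime), no KIR, no
temperature scaling, single compartment, current (not conductance) inputs.
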