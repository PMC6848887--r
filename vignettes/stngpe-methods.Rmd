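---
title: "Model and methods: the stngpe subthalamo-pallidal network simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the stngpe subthalamo-pallidal network simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`stngpe` simulates the reciprocally connected subthalamic nucleus (STN) -
external globus pallidus (GPe) loop with multicompartment conductance-based
neurons, short-term-plastic synapses, a metabotropic GABA-B cascade, and
surrogate cortical (CTX) and indirect-pathway striatal (iMSN) spike sources,
in a control and a parkinsonian (dopamine-depleted) parameter state. Its
purpose is to study how beta-band (13-30 Hz) oscillations arise in the loop:
weak autonomously generated rhythms, resonance with oscillatory cortical
input, and the amplifying or suppressing role of striatal beta input at
different phase offsets.

# The model

## Cable equation and integration

Each neuron is a tree of cylindrical compartments obeying the branched cable
equation: membrane capacitance `c_m` (1 uF/cm^2), specific axial resistance
`R_a` (150 ohm cm), passive leak (`g_m` = 5e-5 S/cm^2 to `E_m` = -60 mV), a
set of voltage- and calcium-gated ionic currents `g-bar * m^p h^q (v - E)`,
and synaptic currents. Axons are not simulated; spikes detected at the soma
(-10 mV upward crossing, 1 ms refractory guard) reach target synapses after
a fixed projection delay. The passive membrane parameters are not fixed by
the tabulated channel and synapse data, so standard values are used and
every one of them is an argument of `build_reduced_morphology()`.

Voltages advance by backward Euler at a fixed `dt` = 0.025 ms: ionic and
synaptic conductances are frozen over the step and enter the implicit
branched-cable solve (Hines elimination, exact for the linearized system),
which is unconditionally stable. Gates follow staggered exponential-Euler
updates, exact for the gate ODE at frozen voltage; the compiled engine reads
gate kinetics from 0.25 mV-grid lookup tables computed by the same R
functions the tests exercise, so the reference and compiled paths agree by
construction. Halving `dt` leaves the early spike times of a
current-driven STN cell converged to a fraction of a millisecond and its
spike count to a few percent (tested); over long horizons the first-order
integrator accumulates limit-cycle phase drift, as fixed-step
conductance-based simulators do. Membrane noise is a Gaussian
current at the soma redrawn every step (SD 0.1 nA in STN, 0.0075 nA in GPe;
the source description leaves the unit open, and nA at the soma reproduces
the intended "similar voltage noise despite lower input resistance"
relation). Initial voltages are uniform per cell, -60 to -70 mV in STN and
-63 to -73 mV in GPe, with gates at steady state and shell calcium at rest.

## Morphologies

The original cell models use reconstructed morphologies that are not
redistributable; `stngpe` substitutes parametric reduced morphologies (and
can read SWC): a soma cylinder plus unbranched tapering dendrites (STN:
3 x 300 um; GPe: 4 x 400 um plus an axon initial segment), discretized into
equal segments. Path distance from the soma drives everything the full
morphology would: channel-density gradients, the distal (x >= 100 um) and
proximal (x < 120 um STN, < 200 um GPe) synapse placement rules, and the
thick/medium/thin dendritic calibre tags (by thirds of the branch length)
that set the GPe high-voltage-activated calcium density. The default
discretization is 6 segments per branch; the reduced "desk" profile uses 4,
which changes no placement rule and alters spike times only marginally.

## Channel library

GPe kinetics are fully tabulated in an eight-parameter sigmoid form
(steady-state Boltzmann with offset `m0`; two-exponential bell time
constant) and are implemented verbatim. The STN table mixes Traub-style
rate equations (NaF, KDR; interpreted in rest-shifted voltage, shift
-60 mV), explicit steady-state/time-constant forms (Kv3.1, HCN, CaL), a
calcium-activated sKCa gate, and a Wang-style T-type current with coupled
slow inactivation `(s, d)` and open fraction `r^3 s`.

Several printed entries are ambiguous or internally inconsistent; the
resolutions adopted (each exposed as plain parameters in `stn_channels()` /
`gpe_channels()`, serializable with `write_channel_config()`):

* **STN persistent sodium (NaP)** is listed without gating. It is
  implemented as an instantaneous Boltzmann activation (midpoint -52 mV,
  slope 3 mV) chosen so that the tabulated density produces the autonomous
  ~10 Hz irregular pacemaking characteristic of the source cell model.
* **CaL calcium-dependent inactivation time constant** is printed as
  "1220" without interpretable units. It is implemented as 122 ms: with
  1220 ms the cell spends most of its time in non-terminating depolarized
  plateaus under physiological synaptic input, contrary to the
  self-terminating plateau/burst behaviour of the source model.
* **CaN** is printed with current `q^2` but a single slow gate `u` whose
  steady state decreases with voltage. It is read as `q^2 u` with `q` an
  instantaneous high-voltage activation (midpoint -20 mV, slope 7 mV, the
  tabulated GPe CaHVA activation) and `u` the printed slow inactivation.
* **CaT** implements the coupled `(s, d)` inactivation scheme whose rate
  constants the table lists even though the current expression reads
  `r^3 s`; the pair is integrated jointly and conserves `s + d + w = 1`.
* **GPe NaP density** is tabulated as 10.15e-3 S/cm^2, which holds the cell
  at a stable depolarized fixed point (~-15 mV) for any density above about
  1e-3 with these kinetics; 3e-4 S/cm^2 restores autonomous pacemaking
  (~13 Hz) and is used instead.
* **GPe sKCa** appears in the membrane equation but has no table row; it
  reuses the calcium-activated gating of the STN sKCa (faster calcium shell,
  tau 1 ms) at 2e-4 S/cm^2.
* **Kv3.1 time constant** is read as the bell `18.7 / (exp(-(v+28)/6) +
  exp((v+4)/16))` ms.
* **CaL dendritic density range** ([1.21, 18.7]e-4 S/cm^2) is mapped
  proximal-high to distal-low, concentrating L-type conductance
  peri-somatically. The ascending alternative co-locates peak L-type
  density with the distal NMDA synapses and produces runaway dendritic
  plateau potentials (cells spending much of their time depolarized above
  -45 mV), inconsistent with the source model's self-terminating plateaus;
  the table does not fix the ordering.

Calcium channels reverse at the Nernst potential of a 0.1 um sub-membrane
shell (STN: rest 1e-4 mM, tau 185.7 ms; GPe: rest 5e-5 mM, tau 1 ms;
external 2 mM; 35 C). Reversals: Na +50, K -90, HCN -30 mV, all
configurable. Temperature enters only the Nernst factor; no Q10 scaling.

## Synapses

All receptors share the dual-exponential conductance `g-bar (B - A)` with
event amplitudes scaled by Tsodyks-Markram resources: on each afferent
spike the running release probability is facilitated first
(`U += U1 (1 - U)`), the release fraction `r = U R` is removed from the
resource pool, and `A`, `B` jump by `f_peak r` so an isolated event peaks at
exactly `g-bar r` (tested to 0.5%). `U` initializes at 0, making `U1` the
first-pulse release probability. NMDA receptors carry the standard
magnesium-block sigmoid; GABA-B receptors drive a G-protein pool
(`dG/dt = K3 (B - A) - K4 G`) whose concentration gates the conductance
through a Hill function (n = 4, Kd = 1.4). The parkinsonian prolongation of
GABA-B decay (+2 ms) applies to the `tau_decay` of the driving `B - A`
profile, the only millisecond-scale decay constant of that synapse.

Projection kinetics, plasticity, delays (CTX->STN 5.9, GPe->STN 2,
STN->GPe 2, GPe->GPe 0.5, iMSN->GPe 5 ms) and per-synapse conductances
follow the tabulated values in `projection_params()`. The tabulated
conductances were hand-tuned against the original implementations and their
absolute units are not fixed; on this package's reduced morphologies they
are recalibrated once by fixed factors (CTX AMPA x4.2, CTX NMDA x0.07,
STN->GPe x2.0) with two criteria settled before any network-level result
was inspected as a target: (i) parkinsonian population rates inside the
experimentally reported ranges (STN 17-37 Hz, GPe near 14.6 Hz), the same
criterion the original tuning used, and (ii) AMPA-dominated cortical drive
with an NMDA:AMPA per-event charge ratio near 1.4, in the physiological
range - under the raw tabulated ratios NMDA carries roughly seventy times
the AMPA charge and clamps STN cells in depolarized plateaus. The baseline
excitation-inhibition ratio and the STN-GPe phase relation were left
emergent.

## Network and the parkinsonian state

Populations: 50 STN + 100 GPe biophysical cells (10 + 20 in the desk
profile), an additional 10% of each as Poisson surrogate spike sources, and
1000 CTX + 2000 iMSN generators (200 + 400 desk). Each target cell draws a
fixed number of afferents without replacement (STN: 20 CTX + 8 GPe; GPe:
10 STN + 6 GPe collaterals + 30 iMSN); each cortical afferent places a
distal AMPA + slow-NMDA pair and a proximal fast-NMDA synapse, pallidal
afferents place proximal GABA-A + GABA-B pairs, subthalamic afferents
distal AMPA, striatal afferents proximal GABA-A.

`apply_state()` switches control to parkinsonian atomically: surrogate
rates (STN 14.6 -> 29.5 Hz, GPe 33.7 -> 14.6 Hz, iMSN 1.5 -> 6.64 Hz),
GPe->STN GABA-A/GABA-B x1.5 with GABA-B decay +2 ms, cortical afferents
pruned to 70% with survivors rescaled by `strengthening_ratio / 0.7`
(the AMPA/NMDA current-scaling ratio of the underlying physiology is not
printed in the source; default 1, configurable), HCN x0.5 in both classes,
STN->GPe AMPA x1.5, GPe->GPe GABA-A/GABA-B x1.5, and iMSN->GPe U1 and
GABA-A x1.5. A field-by-field diff against the control network (tested)
shows no other changes. In simulations with striatal oscillatory bursting,
the facilitating iMSN->GPe synapses are compensated to 40% of baseline
conductance to keep GPe rates physiological.

## Surrogate spike sources

Non-oscillatory inputs are homogeneous Poisson (CTX at 10 Hz, four 2.5 Hz
neurons folded per generator). Oscillatory bursting adds, per cycle of a
regular oscillation, a burst in a fresh random 10% of the generators with a
common onset, a variable spike count (uniform 4-7; reduced when the cycle
cannot contain the burst) and intra-burst intervals uniform in [5, 6] ms;
background spikes in a window centred on each burst (1.5 x the maximal
burst duration) are deleted. The striatal offset protocol delays burst
onsets by the commanded fraction of the period. The spikes-per-burst range
and deletion-window width are not fixed by the source description; the
defaults above produce bursts the >= 4 spike / <= 20 ms ISI detector
recognizes and avoid implausibly short background intervals next to bursts.

# Analyses

Population spectra are mean Welch periodograms of the somatic voltages
(2 s Hann segments, 50% overlap, 0.5 Hz resolution). The instantaneous
phase of a population is the analytic-signal angle of its mean somatic
voltage after zero-phase (forward-backward) 4th-order Butterworth
band-passing in an 8 Hz band; the band centres on the 13-30 Hz argmax of
the reference population (GPe by default) or on the input frequency when an
exogenous oscillation is applied. Traces are decimated to 1 kHz before
filtering so the normalized band stays numerically well-conditioned; the
analytic signal is built by FFT. Generator populations enter the same
pipeline after convolving their spike trains with a 2 ms biphasic
action-potential template (phase results are template-insensitive, tested).
Per-cell phase vectors are means of unit phasors at spike phases; the
population vector is the vector mean of the per-cell vectors (cells first,
then population). Cells with fewer than 5 spikes are excluded and counted.
Bursts are maximal runs of >= 4 spikes with ISIs <= 20 ms (inclusive).
E/I accounting integrates the absolute excitatory and inhibitory synaptic
currents recorded on three cells per population and scales to the
population size.

For the trend that rising cortical drive shifts the endogenous spectral
peak upward, the band's power-weighted mean frequency
(`spectral_centroid()`) is used rather than the argmax bin: at the short
desk-profile record lengths the argmax bin is dominated by single-bin
noise, while the centroid shows the shift consistently.

# Problem sizes, reproducibility and what the tests show

The desk profile (10 STN + 20 GPe cells, 200 CTX + 400 iMSN generators,
3 s simulated with 1 s discarded; 4 segments per dendrite) is the package's
working size for sweeps; the acceptance script shortens records further to
0.5 s warm-up + 2 s analyzed (one full Welch segment) and repeats every
network condition over three seeds. The full-scale profile (50/100/1000/
2000, 6 s) is available through `sim_profile("full")`. All randomness -
connectivity, placement, initial voltages, surrogate trains, membrane
noise - derives from explicit integer seeds; seeded whole-network runs are
bit-for-bit reproducible (tested).

The synthetic surrogate populations emulate the *rates* and *oscillatory
burst structure* of cortical and striatal input, not correlated
cortico-striatal fine structure, non-stationary beta envelopes, or
topographic connectivity; passing tests therefore demonstrate the network's
response to statistically specified input, not a fit to any recorded data.
At desk scale the quantitative network results (E/I ratio, phase relations,
sweep argmaxima) are noisier than at full scale and are treated as
scaled-down reproductions with tolerances, three seeds each.

# Known limitations

* The STN/GPe channel kinetics are reconstructions of partially ambiguous
  tables; the divergences listed above are deliberate and documented, but
  the cells are not numerically identical to the original published models.
* Arkypallidal GPe neurons, the pallido-striatal loop, local field
  potentials, extrasynaptic GABA-B spillover and stimulation protocols are
  out of scope.
* The GPe model has a depolarization-block attractor near -35 mV; strong
  sustained excitation can silence rather than accelerate it. The
  calibrated operating regime stays clear of it, but extreme sweep values
  can re-enter it.
* The 45-degree STN-to-GPe phase lead of the high-drive autonomous regime
  is reproduced only approximately (the model settles nearer 70-85
  degrees, close to the 60-90 degree range the loop shows in general); the
  loop's effective feedback latency on the reduced morphologies appears
  somewhat longer than in the original cells.
* Under oscillatory cortical bursting the somatic-voltage power at the
  input frequency contains a subthreshold component that grows with the
  cortical conductance; in this reconstruction it can outweigh the
  spike-entrainment component at high conductance scales, so the
  conductance scale maximizing the 20 Hz spectral peak sits higher than
  the scale maximizing phase locking (which peaks at moderate scales, as
  in the source network). At the reduced desk scale the cortico-striatal
  phase-offset profile of STN locking is also shallow, so its argmax is
  identified only to within about one 45-degree grid step per run set.
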