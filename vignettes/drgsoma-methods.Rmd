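---
title: "Model and methods: a biophysical bladder small DRG neuron soma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a biophysical bladder small DRG neuron soma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`drgsoma` simulates the soma of an unmyelinated (C-fibre) urinary bladder
small dorsal root ganglion neuron as a single spherical compartment of
diameter 24 µm with total capacitance 28 pF. The membrane potential obeys

$$\frac{dV_m}{dt} = \frac{1}{C_m}\left(I_{stim} - I_{membrane}\right)$$

where $I_{membrane}$ sums twenty-two mechanisms: a passive leak (1/R_m with
R_m = 10 kΩ·cm²), three voltage-gated Na⁺ channels (fast TTX-sensitive,
slowly inactivating Nav1.8, persistent Nav1.9), four voltage-gated K⁺
channels (slow A-type with dual inactivation, delayed rectifier, KCNQ/M,
Na⁺-activated), two Ca²⁺-activated K⁺ channels (BK, SK with inward
rectification), five voltage-gated Ca²⁺ channels (L, N, P/Q, R, T; all GHK
flux currents), store-operated Ca²⁺ entry, TRPM8, a Ca²⁺-activated Cl⁻
current, the Na⁺/K⁺-ATPase, the plasma membrane Na⁺/Ca²⁺ exchanger and the
plasma membrane Ca²⁺-ATPase (PMCA). All gating follows first-order
Hodgkin–Huxley kinetics $dx/dt = (x_\infty - x)/\tau_x$; gates advance by the
exact exponential solution each step. Temperature is fixed at 22 °C with no
Q10 scaling.

Distinctive kinetic features:

* **Slow A-type K⁺** uses one activation gate and two inactivation gates that
  share a steady state but relax with fast (~25–100 ms) and slow
  (~200–800 ms) time constants, combined as $0.3\,h_{fast} + 0.7\,h_{slow}$.
* **BK** activation is a Boltzmann whose half point and slope are functions
  of pCa: $V_{1/2} = -43.4\,pCa - 203$,
  $sf = 33.88\,e^{-((pCa+5.42)/1.85)^2}$.
* **SK** has two instantaneous gates: Hill-type Ca²⁺ activation
  ($n_H = 5.6$, EC50 = 0.42 µM) and a voltage-dependent inward-rectification
  (IR) gate, a falling Boltzmann whose half point rides on $E_K$ so that
  changing [K]⁺ shifts the rectification range. The instantaneous
  conductance is $g = \bar g\,o\,m$ with IR and $\bar g\,o$ without.
* **L- and N-type Ca²⁺** carry GHK flux currents with Ca²⁺-dependent
  inactivation (Hill sigmoid, midpoint 1 µM); the N-type inactivation is
  incomplete — a fraction $1 - a = 0.2674$ of the h pathway keeps conducting
  under maintained depolarization.

## Intracellular calcium

The cytoplasm is discretized into 12 concentric shells of equal radial
thickness except the outermost at half thickness (the near-membrane
compartment convention of reference compartmental simulators; the source
model fixes only the shell count and volume fractions, so the radial layout
is this package's choice and a known source of small quantitative
deviation). Each shell splits 81% cytosol / 12% ER / 7% mitochondria. Per
shell, free cytosolic Ca²⁺ follows

$$\frac{\partial [Ca]_i}{\partial t} = \frac{1}{1+\beta}
  \left(J_{Membrane} - J_{PMCA} + J_{ER} + J_{MT}\right) + J_{Diffusion}$$

with a fixed endogenous rapid-buffer ratio β = 370; membrane influx and the
PMCA act on the outermost shell only. Radial diffusion is Fickian with the
buffered diffusivity $D_{Ca}/(1+\beta)$ applied exactly once, inside the
diffusion operator (the printed equations are ambiguous on whether buffering
divides diffusion once or twice; we follow them literally). The ER update
uses the fluxes in cytosolic concentration units directly, as printed,
without a cytosol/ER volume-ratio factor. The ER carries SERCA uptake (Hill,
n = 2), IP3R release (cubed open-probability with Ca²⁺/IP3 activation and a
slow Ca²⁺-inhibition gate), ryanodine-receptor Ca²⁺-induced Ca²⁺ release
with a hard activation threshold at 600 nM, and a leak. Mitochondria carry
MCU uptake (Hill, n = 2.3) and MNCX release (Na⁺³/Ca²⁺ saturation kinetics).
IP3 diffuses between shells and degrades first-order to its resting 160 nM.
Indicator dyes (Fura-2, Indo-1, Fura-FF, mtPericam) enter as additional
rapid buffers: they add $\beta_{dye}$ to the rate divisor and replace
$D_{Ca}$ by $D_{eff} = (D_{Ca} + \beta_{dye}D_{dye})/(1+\beta+\beta_{dye})$.

The PMCA is an explicit two-reaction scheme (bind cytosolic Ca²⁺, release it
outside). The bound and free densities evolve by both reactions (total
density conserved, advanced implicitly because the binding reaction is
stiff); the cytosol loses Ca²⁺ through the net binding flux, which keeps the
shell mass accounting exact, while the reported pump flux is the net release
flux — the two coincide at steady state, the regime the calibration uses.
The pump's extrusion current is part of the membrane current for the voltage
equation but is excluded from the Ca²⁺ current fed to the shell system,
which already contains the pump flux explicitly.

## Resting-state calibration

Four derived quantities close the model at its resting point
(V = −53.5 mV, [Ca]ᵢ = 136 nM, [Ca]_ER = 0.4 mM, [Ca]_MT = 200 nM):

1. the ER leak factor is solved so SERCA uptake balances IP3R + RYR + leak
   release at rest;
2. the MCU maximal rate is rescaled so mitochondrial uptake and MNCX release
   cancel at rest (the two stated maximal rates, both tuned quantities in
   the source model, do not balance on their own; scaling uptake up rather
   than release down keeps the mitochondrial turnover large enough for
   pump-block experiments to resolve);
3. the membrane Ca²⁺ budget is closed: the exchanger is capped at half the
   resting channel influx and the PMCA pump densities are solved from the
   steady two-reaction equations so the pump removes the remainder;
4. the leak reversal E_pas is solved so the total membrane current vanishes
   at the target RMP with every gate at steady state. With the default
   densities this yields E_pas ≈ −41.4 mV, matching the reported passive
   calibration (−41.583 mV) closely.

Because the resting balance is a flux balance, it is independent of the
buffer load: loading a dye changes transient amplitudes and decay but not
the resting point, so the same calibration stabilizes dye-loaded runs.

## Densities

The control maximum densities are a documented retuning: the published
per-mechanism supplementary density table was not available to this
implementation, so densities printed in the main text were kept where they
exist for the assembled model (leak 1e-4 S/cm²; BK and SK control 9e-4
S/cm²; the slow KA and KDR validation densities as starting points) and the
remainder were adjusted by bounded scalar search against the reported
control behaviour: single-AP features (overshoot 50.91 mV, amplitude
104.47 mV, half-width 4.52 ms), phasic firing (exactly one spike for
0.24 nA × 800 ms), input resistance (316 MΩ), the single-AP Ca²⁺ transient
(Δ[Ca]ᵢ ≈ 18 nM with Indo-1), and tonic ~20 Hz firing under the inflammation
preset (Nav1.8 0.06, KA 1e-4, KDR 1e-3 S/cm²). The shipped defaults land
within ±10% of all these targets; they are a consistent solution, not a
unique one.

Two gating tables have no published numeric form and ship as synthetic
defaults chosen by the package authors, replaceable through the mechanism
configuration: the SK IR gate's half point and slope factor versus [Ca]ᵢ
(monotone, giving a fully open gate near rest and half block 35–60 mV above
E_K), and the N-type inactivation time constant versus voltage (monotone
100 → 50 ms across the channel's operating range). The thirteen
supplementary mechanisms beyond the nine fully specified channels are
parameterized plug-ins built from the model families of the recordings they
were adapted from, with every constant exposed in configuration.

## Numerics

The integrator is a fixed-step scheme written in C++ (via Rcpp): a
linearized implicit voltage update (the local slope conductance, obtained by
numerical differentiation of the total current, damps the step), exact
exponential gate updates, and explicit shell updates with automatic
sub-stepping whenever a concentration would go non-positive. Voltage-gated
steady states and time constants are evaluated once in R — the single source
of truth for all kinetics — and passed to the core as lookup tables on a
0.05 mV grid; only the Ca²⁺-dependent closed forms (BK half point/slope, SK
gates, CDI) are mirrored in C++ and cross-checked against the R definitions
by tests. The default step is dt = 0.005 ms, at which halving dt changes the
AP overshoot, half-width and AHP trough by under 0.1%. Voltage clamp is
ideal (no series resistance). The model has no stochastic component;
repeated runs are bit-identical.

Degenerate inputs are rejected rather than coerced: non-positive
concentrations, time constants or durations raise classed errors, and the
shell stepper aborts if positivity cannot be restored by sub-stepping.

## Feature conventions

A spike is an upward 0 mV crossing. The RMP is the mean of the 5 ms before
stimulus onset. The AP half-width is measured between the two crossings of
RMP + amplitude/2. The AHP start is the downward crossing of the reference
level after the spike peak — the reference is the RMP for brief stimuli
whose AHP develops after stimulus offset, or the during-stimulus depolarized
baseline for long stimuli (the convention under which a reported AHP trough
can lie above the RMP); both are available in
`extract_ap_features(ahp_reference=)`. AHP₈₀% is the time from AHP start
until 80% of the AHP amplitude has been recovered after the trough. Peak-
mode I-V extraction takes the extremum by absolute value so inward and
outward families share one code path; steady mode averages the final 5% of
the test window. The goodness-of-fit statistic is the residual standard
error $S = \sqrt{\sum r^2 / v}$ with $v = n - n_{params}$, not computed when
$v < 4$.

## What the tests do and do not show

The test-suite problem sizes are the package's own choices: the 20-pulse
10 Hz train for organelle-block orderings, three-point conductance sweeps at
0.9, 2.7 and 4.5 mS/cm² (the three values highlighted in the source
analyses) for the SK-rectification and BK-versus-SK comparisons, and a
3-second high-K window for the monotonicity check. Passing them shows the
model reproduces the reported *control-level electrophysiology and
orderings* — it does not validate the model against raw experimental traces
(no digitized recordings ship with the package), and the supplementary
mechanisms are constrained only through the aggregate behaviour of the
assembled soma. Known limitations: bulk Na⁺ and K⁺ concentrations are
clamped (the Na⁺/K⁺ pump contributes current but ion accumulation is not
tracked); TRPM8 is frozen at 22 °C; there is no IK_Ca current (insufficient
data in the source literature); and morphology beyond the single sphere
(axon, T-junction, satellite glia) is out of scope.
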