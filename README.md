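# drgsoma

Conductance-based simulation of the urinary bladder small dorsal root
ganglion (DRG) neuron soma, for computational neuroscientists and
electrophysiologists studying bladder afferent excitability.

Small (~24 µm) bladder DRG neurons are unmyelinated C-fibre nociceptors.
Their soma expresses more than twenty membrane mechanisms — voltage-gated
Na⁺, K⁺ and Ca²⁺ channels, Ca²⁺-activated K⁺ channels, pumps and
exchangers — and an elaborate intracellular Ca²⁺ apparatus. `drgsoma`
implements the full system as a single spherical compartment:

$$C_m \frac{dV_m}{dt} = I_{stim} - \sum_k I_k(V_m, \text{gates}, [Ca]_i)$$

with Hodgkin–Huxley gating ($dx/dt = (x_\infty - x)/\tau_x$), GHK flux
currents for the Ca²⁺-permeable channels, and a 12-shell radial Ca²⁺ model
(rapid-buffer approximation with β = 370, Fickian diffusion, PMCA pump
kinetics, ER SERCA/IP3R/RYR/leak fluxes, mitochondrial uniporter and
Na⁺/Ca²⁺ exchanger, and indicator-dye corrections). Two features set this
model apart from generic point-neuron models:

* the **SK channel carries inward rectification**: besides Hill-type Ca²⁺
  activation (coefficient 5.6, EC50 0.42 µM) it has an instantaneous
  voltage gate referenced to E_K that shuts off outward current at
  depolarized potentials — which measurably raises repetitive firing rates;
* the **slow A-type K⁺ current has two inactivation components** (fast
  ~25–100 ms and slow ~200–800 ms, weighted 0.3/0.7) sharing one steady
  state.

The package provides protocol engines (current clamp, step/ramp voltage
clamp, high-K⁺ challenge, pulse trains, mechanism blocks, conductance
sweeps), analysis tools (spike counting, AP/AHP features, I-V extraction,
Ca²⁺-transient features, the residual-standard-error goodness-of-fit
statistic *S*), and single-channel validation contexts reproducing the
clamp protocols the constituent channel models were fitted under. Traces
and feature tables are tibbles; results pipe into dplyr and ggplot2
(`autoplot()`, `plot_iv()`, `plot_kinetics()`).

## Worked example

```r
library(drgsoma)

model <- soma_config() |> assemble() |> calibrate_rest()
trace <- current_clamp(model, amplitude_nA = 0.16, duration_ms = 50,
                       delay_ms = 20, post_ms = 150)
extract_ap_features(trace)
#> # A tibble: 1 × 10
#>   rmp_mv n_spikes peak_mv overshoot_mv amplitude_mv duration_ms ahp_peak_mv
#>    <dbl>    <int>   <dbl>        <dbl>        <dbl>       <dbl>       <dbl>
#> 1  -53.5        1    55.8         55.8         109.        4.47       -58.7
#>   ahp_amplitude_mv time_to_ahp_peak_ms ahp80_ms
#> 1             5.18                9.20       NA

input_resistance(model)
#> [1] 290.5661
```

The 0.16 nA × 50 ms clamp elicits exactly one action potential from the
−53.5 mV resting potential, with ~109 mV amplitude, ~56 mV overshoot and a
~4.5 ms half-width — the control phenotype of these neurons (reported:
104.5 mV, 50.9 mV, 4.52 ms). The input resistance from a −0.01 nA clamp is
~291 MΩ (reported: 316 MΩ; dissociated-cell range 175–581 MΩ). Longer
suprathreshold clamps stay phasic (a single spike in 800 ms), while the
inflammation preset —

```r
inflamed <- inflammation_preset(model)   # Nav1.8 up, KA and KDR changed
count_spikes(current_clamp(inflamed, 0.12, 1000))
#> [1] 21
```

— fires tonically at ~20 Hz, as in neurons from inflamed bladders.
`autoplot(trace)` plots the spike and, when it varies, the outer-shell
[Ca]ᵢ; `conductance_sweep()` tabulates how AP/AHP features and spike counts
respond to SK or BK conductance.

A thin command-line front end ships in `inst/cli/drgsim.R`
(`presets`, `simulate`, `validate-channel`, `features`, `sweep`).

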