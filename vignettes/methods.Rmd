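---
title: "Models and methods behind the satmg pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the satmg pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmg)
```

This vignette documents the models, the numerical choices, and the design
decisions behind every module, including the things the synthetic generators
deliberately do *not* emulate.

## Scientific setting

Perineuronal **satellite microglia** — microglia whose soma directly apposes a
neuronal soma, with processes touching or wrapping it — have been proposed as
regulators of neuronal excitability: in intact circuits, neurons carrying a
satellite microglia fire less readily (higher spike threshold, deeper
afterhyperpolarization, flatter firing-rate curve), and this modulation is lost
after traumatic brain injury. The package provides the quantitative layer for
studying that phenomenon: intracellular action-potential (AP) feature
extraction, a network-hyperexcitability latency assay, 3D satellite
classification and morphometry, the group statistics, plus seeded synthetic
generators with exact ground truth so every stage can be validated end to end
without animal data.

## Synthetic current-clamp sweeps

`simulate_neuron_sweeps()` renders one voltage sweep per amplitude of a
`make_step_protocol()` (default: 250 ms steps from −250 to 700 pA in 50 pA
increments at 20 kHz, 100 ms pre / 150 ms post).

**Subthreshold model.** A single RC compartment:
$V(t) = V_\mathrm{rest} + R_\mathrm{in} I\,(1 - e^{-t/\tau_m})$,
with $R_\mathrm{in}$ in MΩ, $I$ in pA (so $R_\mathrm{in} I / 1000$ is in mV),
and $\tau_m$ in ms. Defaults ($R_\mathrm{in} = 120$ MΩ, $\tau_m = 20$ ms,
rest −65 mV) describe a regular-spiking layer-V pyramidal neuron.

**Spiking model.** Spikes are *planted*, not integrated from a conductance
model, so every measured feature has a closed-form planted value:

* First spike 5 ms after step onset; the first instantaneous frequency is
  $f_1(I) = g\,(I - I_\mathrm{rheo})$ with gain $g$ (Hz/pA); successive
  interspike intervals grow geometrically, $\mathrm{ISI}_k =
  \mathrm{ISI}_1\,\rho^{\,k-1}$ ($\rho \ge 1$), planting the adaptation index
  exactly.
* Each spike is a piecewise-linear template: rise from threshold $V_T$ to the
  peak at slope $S_r$, fall at slope $S_f$ to the AHP minimum $V_T - D$, then
  linear relaxation back to $V_T$. Between spikes the trace sits exactly at
  $V_T$, so the planted threshold is exact by construction.
* **Grid snapping:** rise and fall durations are rounded to whole samples.
  Without this, template breakpoints would alias against the 20 kHz grid and
  peaks could be clipped by several millivolts. The truth table therefore
  reports the *effective* slopes $S_r^\mathrm{eff}, S_f^\mathrm{eff}$ and the
  closed-form half width $\tfrac{A}{2}(1/S_r^\mathrm{eff} +
  1/S_f^\mathrm{eff})$, where $A$ is the spike amplitude.
* The AHP relaxation always returns fully to $V_T$ before the next onset
  (compressed if the next spike arrives before the nominal recovery time), so
  every spike rises from exactly the planted threshold. Configurations whose
  template does not fit the planted ISI raise an error rather than rendering a
  distorted trace.

**Not emulated:** channel noise and stochastic firing, spike-height
accommodation, sag/rebound, bridge-balance artifacts, electrode drift. The
additive measurement noise is white Gaussian (default 0.1 mV).

## Feature extraction

`detect_spikes()` defines an AP as a positive-slope 0 mV crossing (linearly
interpolated, 1 ms dead time). `passive_properties()` takes input resistance
from the steady-state deflection of the −50 pA sweep (mean over the last 20 %
of the step minus the pre-step baseline). `qc_gate()` excludes recordings with
access resistance ≥ 20 MΩ (or unmeasured) or input resistance > 200 MΩ.

`ap_waveform_features()` implements the derivative-based feature set:

* **Threshold:** voltage at the maximum of $d^3V/dt^3$ in a 3 ms window before
  the peak (clipped at the previous spike's AHP minimum). The trace is
  smoothed with a 2nd-order Savitzky–Golay filter over 0.35 ms before the
  finite-difference derivatives; the threshold *voltage* is read from the raw
  trace at the located sample, so smoothing cannot bias the reported value.
* **Amplitude** peak − threshold; **half width** time above threshold + A/2
  with interpolated crossings; **AHP** threshold minus the minimum before the
  next spike (last spike: up to the step end); **slopes** extreme raw
  first differences on the up/downstroke.

The analysis sweep is rheobase + 100 pA; if it carries fewer than three APs,
the first sweep with more than three APs is used. `fi_curve()` reports the AP
count and first instantaneous frequency per amplitude, and
`adaptation_index()` the last-over-first ISI ratio (needs ≥ 3 spikes).

Window (3 ms), smoothing span (0.35 ms ≈ 7 samples), and the 1 ms dead time
are defaults chosen for 20 kHz data; all are arguments.

## Network hyperexcitability

`simulate_network_trace()` emulates a slice entering a hyperexcitable state:
noisy baseline (default 0.2 mV SD), sparse sub-criterion synaptic events
(alpha-shaped, < 2 mV), and from a configurable onset recurrent compound
depolarizations — a $\sin^2$ envelope modulated by a 12 Hz ripple so the event
looks polysynaptic; the envelope peak stays within 0.5 mV of the nominal
amplitude. `detect_bursts()` uses the printed criterion: events exceeding
2 mV above baseline (median of the first 10 s), after a 50 ms moving average;
regions closer than 0.2 s merge, regions shorter than 50 ms are dropped.
`latency_to_second_burst()` returns the onset of the second detected burst,
operationalizing "second clearly recurrent burst". Traces default to 1 kHz —
bursts are slow events, and no rate is prescribed for this assay.

## 3D stacks and morphometry

`render_stack()` builds a three-channel (microglia / neuron somata / cfos)
z-stack, default 24×160×160 voxels at 0.5×0.4×0.4 µm. Somata are spheres;
processes are rasterized polyline tubes (radius 0.6 µm). For a planted
satellite pair the microglial soma is placed so the somata interdigitate by
0.8 µm (guaranteeing voxel-level contact after rasterization) and the first
process runs onto the partner soma and wraps a short arc. Non-satellite
microglia keep ≥ 2 µm clearance from every neuron and their processes are
steered ≥ 1.5 µm away from neuron surfaces, so noise-free scenes are
unambiguous by construction. Positions are truth-logged in µm (0-based voxel
index × voxel size).

`segment_stack()` thresholds and labels 26-connected components with a
physical minimum-size filter — a deterministic stand-in for interactive
segmentation. `classify_satellites()` applies both printed criteria in 3D:
the microglial *soma* must contact the neuronal soma AND at least one
*process* must touch it; contact is 26-neighbourhood adjacency within one
voxel. For satellites it reports microglia–neuron volume overlap (and ratios)
and the anisotropy-aware contact surface area. `sholl_profile()` counts
sign-changes of the vertex distance per 1 µm sphere (tangent vertices count
once) after discarding filaments shorter than 0.9 µm. `cfos_positivity()`
calls a neuron positive when its mean soma intensity exceeds the non-soma
median by 2 robust SDs (MAD). `percent_area()` is the 2D stained-fraction
quantification.

**Not emulated:** point-spread blur, depth attenuation, ramified microglia
morphology beyond simple polyline processes, touching neuron somata
(placement enforces separation so segmentation identity is never ambiguous).

## Statistics

`compare_two_groups()` wraps the two-tailed test battery (pooled/Welch t,
exact-when-possible Mann–Whitney and Wilcoxon signed rank, paired t);
nonparametric tests are exact for combined n ≤ 12 without ties.
`rm_one_way_anova()` and `rm_two_way_anova()` are complete-case
repeated-measures analyses (subjects with missing levels are dropped with a
warning and counted — mixed-effects models for unbalanced designs are out of
scope). Because AP counts across 14 current levels violate sphericity
severely (Greenhouse–Geisser ε ≈ 0.1 in the demo cohorts),
`rm_two_way_anova()` also reports Greenhouse–Geisser corrected p values for
the within-stratum effects; the demo and report use them. GG was chosen over
Huynh–Feldt because the estimated ε is far below the 0.75 rule of thumb.
`two_way_anova()` handles balanced crossed designs only, and `bh_adjust()`
applies Benjamini–Hochberg within post-hoc families.

## Cohort presets and effect sizes

`cohort_config()` plants the qualitative satellite-microglia pattern: under
the `"sham"` preset, satellite-apposed (`plusMG`) neurons get +3 mV threshold,
+3 mV AHP depth, a −40 % firing-gain change, and a +25 pA rheobase shift; the
`"tbi"` and `"p2y12"` presets plant no offsets (the modulation is lost). Two
points about these magnitudes:

* They are *configurable defaults, not measured values*. The rheobase shift
  follows from the threshold shift for physiological coherence
  ($\Delta I_\mathrm{rheo} \approx \Delta V_T / R_\mathrm{in}$).
* The gain effect is power-calibrated: with 12 neurons per condition (the
  documented default) the planted group and interaction effects on AP counts
  are detected in ≈ 90 % of seeded runs, which is what a synthetic benchmark
  of this design target requires. Per-neuron jitter SDs (e.g. 15 MΩ on
  $R_\mathrm{in}$, 25 pA on rheobase) are fixed design choices documented in
  `cohort_config()`.

## End-to-end demo

```{r demo, eval = FALSE}
demo <- run_demo(seed = 1)
demo
build_report(demo, "report")
```

`run_demo()` simulates sham and TBI cohorts, summarizes every neuron,
analyses AP counts across current levels with the mixed-design ANOVA, compares
AP features between conditions (Welch t + BH), runs the latency assay
(n = 8 sham vs 6 TBI slices), and renders/analyses one 3D stack.
`build_report()` writes per-analysis TSV tables and a JSON summary. All
problem sizes (12 neurons/group, 8/6 slices, one 160×160×24 stack) are the
package's own demonstration-scale choices, sized so the full demo runs in
seconds.

## Limitations

* Planted spikes mean detection/feature code is validated against *known*
  waveforms, not against biophysical diversity (bursting cells, spikelets,
  depolarization block are absent).
* The burst generator produces stereotyped envelopes; detector performance on
  real polysynaptic discharges with superimposed spiking is untested here.
* Segmentation is global-threshold based; the package does not attempt
  learned pixel classification, and touching cells are avoided by
  construction rather than resolved.
* Repeated-measures analyses are complete-case; unbalanced designs belong to
  mixed-effects models, which are deliberately out of scope.
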