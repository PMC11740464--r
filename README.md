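# satmg

Quantitative pipeline for studying **perineuronal satellite microglia** —
microglia whose soma directly apposes a neuronal soma with processes touching
or wrapping it — and their effect on neuronal excitability.

In intact circuits, neurons carrying a satellite microglia are less excitable:
higher spike threshold, deeper afterhyperpolarization, flatter firing-rate
curve. After traumatic brain injury this modulation is lost. The package
implements the analysis layer needed to quantify that phenomenon, together
with seeded synthetic generators carrying exact ground truth so every stage is
verifiable end to end without animal data:

* **Synthetic data** — current-clamp step sweeps whose action-potential (AP)
  features are planted in closed form (`simulate_neuron_sweeps()`,
  `simulate_cohort()`), long traces with emergent polysynaptic bursts
  (`simulate_network_trace()`), and three-channel 3D stacks with planted
  satellite microglia and cfos positives (`render_stack()`).
* **Intracellular ephys** — spike detection at the 0 mV upward crossing,
  passive properties from the −50 pA step, quality-control gates (Ra ≥ 20 MΩ,
  Rin > 200 MΩ), third-derivative AP threshold, half width, AHP, slopes, F-I
  curves, adaptation index, per-neuron summaries (`summarize_neuron()`).
* **Network excitability** — burst detection with the > 2 mV criterion and
  latency to the second recurrent burst (`detect_bursts()`,
  `latency_to_second_burst()`).
* **3D morphometry** — threshold segmentation into 26-connected components,
  satellite classification requiring both soma *and* process contact, volume
  overlap and contact surface area, Sholl profiles with the 0.9 µm filament
  filter, cfos positivity, percent stained area.
* **Statistics** — two-group test battery (t/Welch/exact Mann–Whitney/
  Wilcoxon), repeated-measures and mixed-design ANOVA with Greenhouse–Geisser
  correction, balanced two-way ANOVA, Benjamini–Hochberg adjustment, report
  generation.

## Worked example

```r
library(satmg)

# one synthetic neuron through the full intracellular pipeline
sweeps <- simulate_neuron_sweeps(neuron_params(), make_step_protocol(),
                                 seed = 7, id = "demo-neuron")
summarize_neuron(sweeps)
#> Neuron 'demo-neuron' (NA): included
#>   VT -45.06 mV, amp 80.1 mV, HW 0.491 ms, AHP 11.91 mV, adapt 2.01

# the seeded end-to-end demonstration: cohorts, latency assay, 3D stack
demo <- run_demo(seed = 1)
demo
#> Synthetic pipeline demo (seed 1)
#>   sham cohort: group p = 4.576e-05, current x group p = 9.33e-05 (AP counts, GG)
#>   tbi cohort: group p = 0.8067, current x group p = 0.8449 (AP counts, GG)
#>   latency sham vs tbi: p = 0.0001088
#>   stack: 50.0% of neurons have a satellite microglia

build_report(demo, "report")   # TSV tables + report.json
```

The demo reproduces the qualitative headline: the satellite-associated
reduction in excitability is statistically detectable in the sham preset
(significant group and current × group effects on AP counts) and absent in
the TBI preset, where no offsets are planted.

The methods vignette (`vignettes/methods.Rmd`) documents the models, the
numerical choices (grid-snapped spike templates, Savitzky–Golay derivative
smoothing, Greenhouse–Geisser epsilon), the preset effect sizes and their
power calibration, and the limitations of the generators.

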