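Package: satmg
Title: Satellite-Microglia Electrophysiology and 3D Morphometry Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative pipeline for studying perineuronal satellite
    microglia and neuronal excitability. Provides seeded synthetic-data
    generators (current-clamp step sweeps with analytically known action
    potential features, long traces with emergent polysynaptic bursts, and
    multi-channel 3D image stacks with planted satellite microglia and cfos
    ground truth), intracellular action-potential feature extraction
    (third-derivative spike threshold, half width, afterhyperpolarization,
    slopes, F-I curves, adaptation), network-hyperexcitability burst-onset
    latency, 3D morphometry (segmentation, satellite classification, volume
    overlap, contact surface area, Sholl profiles, cfos positivity, percent
    area), and a group-statistics layer (t/Welch/Mann-Whitney/Wilcoxon,
    repeated-measures and mixed-design ANOVA, Benjamini-Hochberg adjustment)
    with a reproducible end-to-end demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
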