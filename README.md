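# astromea

Analysis pipeline for multi-channel extracellular recordings from
microelectrode arrays (MEAs), built to quantify how network composition —
for example the share of astrocytes co-cultured with neurons — shapes
electrical activity. Cultures rich in astrocytes fire less, burst less,
lose signal patterning and become harder to predict; demonstrating that
requires going beyond plain spike counts, and this package bundles the
required machinery end to end:

* **Spike & burst analysis** — zero-phase 300-3000 Hz elliptic bandpass,
  `+/- 5 sigma` threshold detection, network-wide cumulative-moving-average
  (CMA) burst detection, and the standard activity metrics (SR, BR, BD,
  % spikes in bursts, ISI, IBI).
* **Complexity-entropy causality plane** — Bandt-Pompe ordinal patterns of
  dimension `M` and lag `tau` give, per channel, the normalized permutation
  entropy `Hs = S[P]/log(M!)` and the statistical complexity
  `Cjs = Q0 * Je[P, Pe] * Hs` (Jensen-Shannon disequilibrium from the
  uniform pattern distribution), separating noise-like channels
  (`Hs -> 1, Cjs -> 0`) from patterned ones.
* **iAAFT surrogate testing** — iterative amplitude-adjusted Fourier
  transform surrogates (exact value distribution, near-exact power
  spectrum, randomized phases) as the linear-stochastic null; empirical
  CDFs of `Hs`/`Cjs` for originals vs surrogates compared with a
  two-sample Kolmogorov-Smirnov test.
* **Waveform classification** — 3 ms spike cutouts, per-channel
  clustering, cluster averaging, five shape features, and classification
  into regular / fast / triphasic / compound / positive spiking
  (RS/FS/TS/CS/PS).
* **Predictability** — random forest on a lagged autoregressive design
  (70/30 contiguous split, one-step-ahead), scored by the Pearson
  correlation between predicted and held-out values.
* **Synthetic MEA generator** — ground-truthed recordings with three
  condition presets (`patterned`, `intermediate`, `irregular`) emulating
  decreasing activity, burstiness, stereotypy and patterning, so every
  stage is testable without laboratory data.

See `vignettes/astromea-methods.Rmd` for the models, parameter choices and
limitations.

## Worked example

Simulate a patterned culture, detect spikes and bursts, and place every
channel on the complexity-entropy plane:

```r
library(astromea)

params <- generator_params("patterned", n_channels = 8, duration_s = 60,
                           sampling_rate = 10000, seed = 11)
sim <- render_recording(params)
cfg <- analysis_config(analysis_window = c(5, 55))
win <- slice_window(sim$recording, 5, 55)

spikes <- detect_spikes(bandpass_spike(win, cfg), k = 5)
bursts <- cma_burst_detect(spikes)
met <- activity_metrics(spikes, bursts)
met$network[, c("sr_hz", "mean_channel_sr_hz", "br_hz", "pct_spikes_in_burst")]
#>   sr_hz mean_channel_sr_hz br_hz pct_spikes_in_burst
#> 1 41.18             5.1475  3.24            63.62312

ce <- ce_plane(ce_preprocess(win, cfg), cfg)
round(colMeans(ce[, c("Hs", "Cjs")]), 3)
#>    Hs   Cjs
#> 0.655 0.333
```

`sr_hz` pools all 8 channels (about 5.1 spikes per channel-second) and
`br_hz` likewise; ~64% of spikes fall inside CMA-detected bursts. The low
entropy / high complexity pair is the signature of patterned activity;
re-running with the `"irregular"` preset moves the channels to the noise
corner (`Hs ≈ 0.999`, `Cjs ≈ 0.001`) and drops the spike rate about
five-fold, the qualitative profile of astrocyte-rich co-cultures.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` ... `06_prediction.R`) that runs these stages over all
three presets and writes the tables under `results/`.

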