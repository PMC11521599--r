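---
title: "Methods: spike, burst, complexity-entropy and predictability analysis of MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike, burst, complexity-entropy and predictability analysis of MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`astromea` analyses multi-channel extracellular voltage recordings from
microelectrode arrays (MEAs), the kind used to characterize how network
composition — for example the fraction of astrocytes co-cultured with
neurons — shapes spiking statistics, signal patterning and predictability.
A recording is a channels x samples matrix in microvolts with a sampling
rate (25 kHz is typical for the hardware this workflow targets); times are
seconds, windows half-open `[start, end)`, sample indices 0-based. The
interchange formats are CSV with a JSON metadata sidecar (portable,
15 significant digits) and RDS (bit-exact); both round-trip through
`write_recording()` / `read_recording()`.

Four analysis chains run off the raw matrix. Unless noted, they operate on
a 100 s analysis window (default 100-200 s of a 5-minute recording), chosen
long enough to estimate ordinal-pattern distributions with `M = 5`
(120 patterns vs ~10^5 embedding vectors) yet short enough to treat the
culture as stationary.

# Preprocessing chains

* **Spike chain** — second-order elliptic bandpass, 300-3000 Hz (0.1 dB
  passband ripple, 40 dB stopband attenuation; the ripple/attenuation pair
  is not dictated by the hardware and is exposed in the configuration).
* **Complexity-entropy chain** — Butterworth lowpass at 40 Hz (order 4),
  then decimation to 1 kHz by keeping every k-th sample.
* **Prediction chain** — Butterworth lowpass at 300 Hz (order 5), then
  decimation to 250 Hz (one sample per 4 ms). The cutoff sits above the
  output Nyquist; this follows the published procedure of retaining spike
  deflections while shrinking the series, and the predictability score is
  unaffected by the aliased residue. We read the original description of a
  "low-cut frequency" for this denoising step as a low-pass cutoff — the
  subsequent 250 Hz resampling only makes sense if low frequencies are
  retained.

All filters are applied forward-backward (zero phase), so spike timing is
not biased; the effective order doubles. Whether a causal or zero-phase
filter was used originally is not documented; at these orders the
difference in spike timing is below one sample. `filtfilt` alone leaves the
startup transient in the output, so each channel is padded by odd
reflection (50 ms or as much as the data allows) and trimmed after
filtering; the spike chain additionally removes the channel mean first,
since DC lies in its stopband.

# Spike detection and burst analysis

Spikes are threshold crossings of the bandpassed signal beyond
`+/- k sigma` with `k = 5`, where `sigma` is the plain standard deviation
of the filtered window (a median-based robust estimate is available as an
option, but the plain deviation is the documented definition we follow).
Each contiguous supra-threshold excursion contributes one spike at its
extremum; events closer than the dead time are merged keeping the larger
one. The dead time defaults to 2 ms — the absolute refractory period — because
the positive afterwave of a regular-spiking waveform peaks ~1 ms after the
trough and can itself exceed 5 sigma, so a 1 ms dead time double-counts it.

Burst detection is the network-wide cumulative-moving-average (CMA)
method: all channels' inter-spike intervals (ISIs) are pooled into one
histogram (5 ms bins, intervals above 1 s clamped into the overflow bin),
the cumulative moving average of the counts is computed, and the burst ISI
threshold is the bin where the CMA has decayed to `alpha1 x max(CMA)`.
`alpha1` follows the published skewness map of the method (CMA-curve
skewness < 1: 1.0; < 4: 0.7; < 9: 0.5; else 0.3). Consecutive spikes with
ISIs at or below the threshold form bursts of at least 3 spikes, delimited
per channel. Two degenerate cases return an empty burst set with a
warning: fewer than two spikes network-wide, and a single-bin ISI
histogram (e.g. a perfectly regular train), where the threshold is
undefined.

The activity metrics are spike rate (SR, Hz), burst rate (BR, Hz), burst
duration (BD, ms), percentage of spikes inside burst intervals, ISIs and
inter-burst intervals (IBIs, burst end to next burst start), reported per
channel and pooled, since the original account is ambiguous about the
pooling level.

# Ordinal patterns and the complexity-entropy plane

For a series `x` and each time `u`, the embedding vector
`(x[u-(M-1)tau], ..., x[u-tau], x[u])` is mapped to the permutation
`(s0, ..., s_{M-1})` of lag indices that orders it:
`x[u - s_{M-1} tau] <= ... <= x[u - s0 tau]`, with ties resolved by
`s_l < s_{l-1}` when the tied values are equal (a constant window maps to
the single pattern `(M-1, ..., 1, 0)`). Relative frequencies over the `M!`
patterns give the distribution `P`. Two summaries are computed per
channel:

* normalized permutation entropy `Hs = S[P] / log(M!)`, with `S` the
  Shannon entropy (natural log internally; `Hs` is base-free) and
  `0 log 0 := 0` — unobserved patterns simply contribute nothing, no
  smoothing is applied;
* statistical complexity `Cjs = Q0 * Je * Hs`, where
  `Je = S[(P+Pe)/2] - S[P]/2 - S[Pe]/2` is the Jensen-Shannon divergence
  from the uniform distribution `Pe` and
  `Q0 = -2 / ( ((N+1)/N) log(N+1) - 2 log(2N) + log N )`, `N = M!`, makes
  the disequilibrium factor reach 1 at its maximum. One widely reprinted
  form of the divergence omits the `/2` inside the first entropy; that form
  is not a divergence (it can exceed valid bounds), so the standard form is
  implemented.

`Cjs` vanishes both for fully random (uniform `P`) and fully ordered
(degenerate `P`) signals and is maximal in between, which is what lets the
(Hs, Cjs) plane separate noise-like from patterned channels. Defaults are
`M = 5` and `tau = 100` samples (100 ms at 1 kHz); the original analysis
calls this lag optimal without stating the criterion, so here it is a
plain configuration value. The hot loop (pattern coding) is C++; a
brute-force permutation matcher in the test suite pins the implementation
to 1e-12.

# iAAFT surrogates and the Kolmogorov-Smirnov comparison

The iterative amplitude-adjusted Fourier transform scheme starts from a
seeded random permutation of the channel and alternates two projections:
impose the original amplitude spectrum in the Fourier domain, then
rank-remap onto the original sorted values. The surrogate therefore keeps
the value distribution exactly and the power spectrum approximately while
randomizing Fourier phases — the null model of a stationary linear
stochastic process seen through a static monotone function. Iteration
stops at an exact rank-order fixed point, when the relative
amplitude-spectrum discrepancy drops below 3.5e-3 (periodogram error
~7e-3 — the surrogate is spectrally faithful, and further iterations only
polish digits the analysis never uses), when the discrepancy stalls
(relative improvement per iteration below 5%, checked after 10
iterations), or at the 1000-iteration cap. These practical rules matter
because on structured signals the exact fixed point is effectively
unreachable while the discrepancy keeps improving by fractions of a
percent forever; every stop leaves the periodogram error well within the
1e-2 quality bound the tests enforce. FFTs go through FFTW with cached
measured plans and the rank remap uses a radix argsort; one surrogate of a
100 s / 1 kHz channel takes ~0.15 s, so the full 60-channel x
49-surrogate ensemble stays under ten minutes on one core.

Per channel, `n = 49` surrogates receive the same preprocessing and
complexity-entropy analysis as the original; surrogate measures are pooled
(per recording by default — pooling across recordings of a culture is a
grouping choice left to the caller) and original-vs-surrogate empirical
CDFs are compared with a two-sample Kolmogorov-Smirnov test:
`D = sup |F_a - F_b|`, p-value from the asymptotic Kolmogorov distribution
at effective size `n_a n_b / (n_a + n_b)`, rejection at `p < 0.05`. The
asymptotic form is appropriate at the sample sizes involved (>= 49); the
test suite cross-checks it against the reference implementation and
verifies the decision's calibration under the null, where the discreteness
of `D` at equal sample sizes makes the p-value distribution lumpy even
though the rejection rate is nominal. No multiple-testing correction is
applied across channels or measures, matching the original analysis.

# Waveform features and classification

Cutouts span 1 ms before to 2 ms after each detected spike's peak (the
sample count follows from the actual rate — 76 samples at 25 kHz; published
accounts quoting "60 samples" for 3 ms imply 20 kHz, so the window is
defined in time, not samples). Boundary spikes are skipped and counted
rather than padded, because the baseline is the mean of the first and last
samples and padding would distort it. Cutouts are clustered per channel by
k-means on unit-norm waveforms with k picked by average silhouette over
2..6 (a subsample is used for the silhouette when cutouts are plentiful;
k = 1 is declared when the best silhouette is below 0.2 or the cutouts are
nearly identical). Full superparamagnetic wavelet sorting is out of scope
here — clustering only serves to average similar waveforms, and the
clusterer is swappable.

Averaged waveforms yield five features: signed baseline-to-peak amplitude;
the absolute ratio of the opposite-sign extremum preceding the peak ("1st
peak") to the peak; the amplitude slope `(peak - 1st peak)/(t_peak -
t_1st)`; the peak-to-peak time (1st peak to the first opposite-sign local
extremum after the peak, the "2nd peak"); and the spike duration (peak to
2nd peak). The 2nd peak must clear a prominence of 5% of the main
amplitude; when absent, the duration runs to the window end and the result
is flagged. Classification: positive amplitude is PS; otherwise compound
(CS) when two or more troughs reach 30% prominence at >= 0.3 ms
separation, else triphasic (TS) when both positive phases reach 15% of the
main amplitude, else fast-spiking (FS) when the spike duration is under
0.5 ms, else regular-spiking (RS). The CS -> TS -> FS -> RS precedence and
the numeric thresholds are implementation defaults (the published decision
tree does not print them); all negative-branch criteria are ratios or
durations, so the classification is scale-invariant.

# Predictability

The published procedure trains a random-forest regressor on the first 70%
of each 250 Hz channel and tests on the last 30%, without stating the
regressor's inputs; the only framing consistent with a contiguous 70/30
split of a single series is autoregressive, so row `i` of the design holds
the previous `n_lags = 20` samples (80 ms of history) and the target is
the next sample, predicted one step ahead from true lags. "No limit on the
number of trees" does not map to a fixed-size ensemble API; the default is
100 trees of unlimited depth (the bundled analyses use 50 for speed), seeded
and single-threaded for reproducibility. The score is the Pearson
correlation between predictions and held-out values — reported in parts of
this literature under the label "R^2" despite ranging over [-1, 1]; the
package calls the column `pearson_r`. A constant test segment (or constant
predictions) is flagged and scored `NaN`.

# The synthetic generator: what it emulates, and what it does not

Every stage is tested against ground truth from `render_recording()`,
which simulates one culture per condition preset:

| preset | tonic rate | bursts | templates | slow field |
|---|---|---|---|---|
| patterned | 2 Hz | 0.4 Hz, periodic (20 ms onset jitter), 8 spikes @ 10 ms | one class per channel, 80 uV, 3% jitter | 40 uV deflection per burst + 15 uV sawtooth rhythm @ 1.5 Hz |
| intermediate | 1.5 Hz | 0.25 Hz, Poisson, 6 spikes @ 15 ms | one class per channel, 70 uV, 10% jitter | 20 uV + 6 uV rhythm @ 1.2 Hz |
| irregular | 0.8 Hz | 0.05 Hz, Poisson, 4 spikes @ 25 ms | class per spike, 60 uV, 30% jitter | 5 uV, no rhythm |

Channel noise is white Gaussian at 10 uV, so the patterned preset's spikes
sit at SNR 8. Spike shapes are sums of Gaussian-windowed phases per class
(RS, FS, TS, CS, PS) with exactly-zero endpoints, so the feature extractor
recovers the generating amplitude exactly in the noise-free case. Each
burst adds a slow negative field deflection whose width (0.10-0.18 s)
matches the sub-second population-burst field potentials of real cultures;
widths far below the ordinal embedding span (400 ms at the default M, tau)
cannot create ordinal structure, which is why the deflection operates on
this time scale. The patterned and intermediate presets additionally carry
an ongoing slow rhythm with a truncated-sawtooth waveform: its harmonics
are phase-locked, and that nonlinear phase structure — not the spectrum or
the value distribution, both of which iAAFT preserves — is what
distinguishes patterned activity from its surrogates. A generator whose
"patterning" were mere burst intermittency would be indistinguishable from
its own surrogates (or even less entropic than them), and the surrogate
test would have nothing to detect.

The generator deliberately omits: biophysics (no membrane or synapse
models), electrode geometry and spike propagation, correlated noise across
channels, non-stationarity over the recording, overlapping-unit spike
sorting ambiguity, and development over days in vitro. Passing tests
therefore show that the pipeline recovers the statistics it was pointed
at under controlled conditions — not that it resolves real biological
recordings of arbitrary quality. Preset parameters are implementation
choices made once to place the three conditions in the qualitative order
reported for pure neuronal vs astrocyte-rich cultures (decreasing SR, BR
and patterning; increasing entropy; decreasing predictability); they are
not measured values from any dataset.

# Numerical choices and degenerate inputs

* Seeds: one global seed is fanned out per stage and channel via a keyed
  hash (`stage_seed()`), so stages are decoupled and the full run is
  reproducible; all C++ randomness is injected from R.
* Ordinal ties follow the smaller-lag-later rule above; constant windows
  are valid inputs, not errors.
* `sigma = 0` channels abort spike detection (degenerate input), flat
  waveforms abort feature extraction, zero-variance series abort Pearson
  correlation; constant prediction segments are flagged rather than
  scored.
* Decimation is sample-keeping after an explicit lowpass; non-integer
  rate ratios are errors rather than silent resampling.
* The bundled `analysis/` drivers run at desk scale (16 channels x 120 s
  at 10 kHz; 12 surrogates per channel; predictability on a six-channel
  subset), sizes chosen so the whole workflow
  re-runs in minutes while every estimate remains stable; the acceptance
  script exercises the full 60-channel x 49-surrogate ensemble.

# Known limitations

* The burst detector's `alpha1` map is the published one, but the CMA
  skewness is computed on the CMA curve itself; pathological ISI mixtures
  could select a different alpha than other implementations.
* The KS p-value is asymptotic; for very small pools (a handful of
  channels) an exact test would be preferable.
* k-means clustering assumes roughly spherical waveform clusters after
  normalization; strongly overlapping units would need a real sorter.
* One-step-ahead prediction is implemented; direct multi-step horizons are
  a configuration stub left for future work.
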