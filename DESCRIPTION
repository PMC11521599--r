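Package: astromea
Title: Spike, Burst, Complexity-Entropy and Predictability Analysis for
    Microelectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel extracellular recordings
    from microelectrode arrays (MEAs), aimed at quantifying how network
    composition (for example neuron/astrocyte co-culture ratios) shapes
    electrical activity. Provides threshold spike detection on elliptically
    bandpassed signals, network-wide cumulative-moving-average burst
    detection with the standard activity metrics (spike rate, burst rate,
    burst duration, percentage of spikes in bursts, inter-spike and
    inter-burst intervals), Bandt-Pompe ordinal-pattern distributions and
    the complexity-entropy causality plane, iterative amplitude-adjusted
    Fourier transform (iAAFT) surrogate testing with empirical-CDF /
    Kolmogorov-Smirnov comparison, averaged spike-waveform feature
    extraction and five-class shape classification, and autoregressive
    random-forest predictability scoring. A ground-truthed synthetic MEA
    recording generator with three condition presets makes every stage
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    graphics,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
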