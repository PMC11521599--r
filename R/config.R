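#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis pipeline with the
#' defaults used throughout: a 300-3000 Hz second-order elliptic bandpass
#' before spike detection with a +/- 5 sigma threshold, the 100-200 s
#' analysis window, a 40 Hz lowpass + 1 kHz resampling before ordinal
#' complexity-entropy analysis with embedding dimension M = 5 and lag
#' tau = 100 samples, 49 iAAFT surrogates per channel, 3 ms spike cutouts
#' (1 ms pre / 2 ms post), and a 300 Hz 5th-order Butterworth lowpass +
#' 250 Hz resampling before autoregressive random-forest prediction with a
#' 70/30 contiguous train-test split.
#'
#' @param spike_band bandpass edges in Hz for spike detection.
#' @param spike_filter_order elliptic filter order (applied forward-backward,
#'   so the effective order is doubled).
#' @param spike_ripple_db passband ripple of the elliptic design, dB.
#' @param spike_atten_db stopband attenuation of the elliptic design, dB.
#' @param spike_threshold_k detection threshold in multiples of the filtered
#'   signal's standard deviation.
#' @param spike_dead_time_ms minimum separation between detected spikes, ms.
#' @param analysis_window `(start, end)` seconds of the analysis window.
#' @param ce_lowpass_hz lowpass cutoff before complexity-entropy analysis, Hz.
#' @param ce_rate_hz target rate for complexity-entropy analysis, Hz.
#' @param ce_m ordinal embedding dimension M (>= 2).
#' @param ce_tau ordinal embedding lag in samples (>= 1).
#' @param n_surrogates iAAFT surrogates per channel.
#' @param surrogate_max_iter iteration cap of the iAAFT scheme.
#' @param alpha significance level of the Kolmogorov-Smirnov decision.
#' @param cutout_pre_ms,cutout_post_ms spike cutout extent around the peak, ms.
#' @param burst_bin_ms ISI histogram bin width for burst detection, ms.
#' @param burst_max_isi_ms ISI histogram cap, ms.
#' @param burst_min_spikes minimum spikes per burst.
#' @param waveform_thresholds named list of classifier thresholds, see
#'   [classify_waveform()].
#' @param predict_lowpass_hz lowpass cutoff before prediction, Hz.
#' @param predict_filter_order Butterworth order of that lowpass.
#' @param predict_rate_hz target rate for prediction, Hz.
#' @param train_fraction fraction of samples in the (contiguous) training set.
#' @param n_lags autoregressive order of the lagged design, samples.
#' @param n_trees trees in the random-forest regressor.
#' @param seed global seed, fanned out per stage via [stage_seed()].
#'
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(spike_band = c(300, 3000),
                            spike_filter_order = 2,
                            spike_ripple_db = 0.1,
                            spike_atten_db = 40,
                            spike_threshold_k = 5,
                            spike_dead_time_ms = 2,
                            analysis_window = c(100, 200),
                            ce_lowpass_hz = 40,
                            ce_rate_hz = 1000,
                            ce_m = 5,
                            ce_tau = 100,
                            n_surrogates = 49,
                            surrogate_max_iter = 1000,
                            alpha = 0.05,
                            cutout_pre_ms = 1,
                            cutout_post_ms = 2,
                            burst_bin_ms = 5,
                            burst_max_isi_ms = 1000,
                            burst_min_spikes = 3,
                            waveform_thresholds = list(
                              fs_max_duration_ms = 0.5,
                              triphasic_ratio = 0.15,
                              cs_prominence = 0.3,
                              cs_min_separation_ms = 0.3,
                              second_peak_prominence = 0.05),
                            predict_lowpass_hz = 300,
                            predict_filter_order = 5,
                            predict_rate_hz = 250,
                            train_fraction = 0.7,
                            n_lags = 20,
                            n_trees = 100,
                            seed = 1L) {
  stopifnot(length(spike_band) == 2, spike_band[1] > 0,
            spike_band[1] < spike_band[2],
            spike_threshold_k > 0,
            length(analysis_window) == 2,
            analysis_window[1] < analysis_window[2],
            ce_m >= 2, ce_tau >= 1,
            n_surrogates >= 1, surrogate_max_iter >= 1,
            alpha > 0, alpha < 1,
            train_fraction > 0, train_fraction < 1,
            n_lags >= 1, n_trees >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Deterministic per-stage seed
#'
#' Fans a global seed out into stage-specific substreams keyed by the stage
#' name, so independent pipeline stages draw from decoupled, reproducible
#' random streams.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"simulate"`, `"surrogate"`).
#' @param index optional extra index (e.g. channel or surrogate number).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% mod
  for (b in utf8ToInt(stage)) h <- (h * 69069 + b) %% mod
  h <- (h * 69069 + as.numeric(index)) %% mod
  as.integer(h)
}
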