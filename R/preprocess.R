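#' Filter specification
#'
#' Thin container describing one of the two filter designs used by the
#' pipeline: an elliptic bandpass (spike chain) or a Butterworth lowpass
#' (complexity-entropy and prediction chains). Frequencies in Hz; the
#' design is realized against a concrete sampling rate at application time.
#'
#' @param kind `"elliptic-bandpass"` or `"butterworth-lowpass"`.
#' @param order filter order (the zero-phase forward-backward application
#'   doubles the effective order).
#' @param band numeric: `c(low, high)` Hz for bandpass, single cutoff Hz
#'   for lowpass.
#' @param ripple_db passband ripple (elliptic only), dB.
#' @param atten_db stopband attenuation (elliptic only), dB.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("elliptic-bandpass", "butterworth-lowpass"),
                        order, band, ripple_db = 0.1, atten_db = 40) {
  kind <- match.arg(kind)
  if (kind == "elliptic-bandpass") {
    stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  } else {
    stopifnot(length(band) == 1, band > 0)
  }
  structure(list(kind = kind, order = order, band = band,
                 ripple_db = ripple_db, atten_db = atten_db),
            class = "filter_spec")
}

# realize a filter_spec at a sampling rate -> signal::Arma coefficients
design_filter <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (max(spec$band) >= nyq)
    stop(sprintf("filter edge %g Hz >= Nyquist %g Hz", max(spec$band), nyq))
  if (spec$kind == "elliptic-bandpass") {
    signal::ellip(spec$order, Rp = spec$ripple_db, Rs = spec$atten_db,
                  W = spec$band / nyq, type = "pass")
  } else {
    signal::butter(spec$order, W = spec$band / nyq, type = "low")
  }
}

# zero-phase (forward-backward) filtering along each channel row, with
# odd-reflection end padding (50 ms or as much as the data allows) so the
# filter's startup transient is confined to the discarded pads
apply_filter <- function(rec, spec) {
  filt <- design_filter(spec, rec$sampling_rate)
  n <- ncol(rec$data)
  pad <- min(n - 1L, max(100L, round(0.05 * rec$sampling_rate)))
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- rec$data[ch, ]
    xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    yp <- signal::filtfilt(filt, xp)
    out[ch, ] <- yp[(pad + 1L):(pad + n)]
  }
  raw_recording(out, rec$sampling_rate, rec$channel_ids, rec$t0)
}

# keep every k-th sample after lowpassing; output length floor(n / k)
decimate_rec <- function(rec, target_rate) {
  factor <- rec$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop(sprintf("sampling rate %g Hz is not an integer multiple of %g Hz",
                 rec$sampling_rate, target_rate))
  factor <- round(factor)
  if (factor == 1) return(rec)
  idx <- seq(1, by = factor, length.out = floor(ncol(rec$data) / factor))
  raw_recording(rec$data[, idx, drop = FALSE], target_rate,
                rec$channel_ids, rec$t0)
}

#' Spike-chain preprocessing: elliptic bandpass
#'
#' Applies the second-order 300-3000 Hz elliptic bandpass (forward-backward,
#' hence zero-phase) used before threshold spike detection. The DC component
#' and slow local field potentials fall in the stopband.
#'
#' @param rec a [raw_recording()].
#' @param config an [analysis_config()] (band edges, order, ripple,
#'   attenuation).
#' @return the filtered [raw_recording()], same shape and rate.
#' @export
bandpass_spike <- function(rec, config = analysis_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  spec <- filter_spec("elliptic-bandpass", order = config$spike_filter_order,
                      band = config$spike_band,
                      ripple_db = config$spike_ripple_db,
                      atten_db = config$spike_atten_db)
  # DC is in the stopband; removing the channel mean first keeps the
  # filter's startup transient from carrying the offset into the output
  centered <- raw_recording(rec$data - rowMeans(rec$data),
                            rec$sampling_rate, rec$channel_ids, rec$t0)
  apply_filter(centered, spec)
}

#' Complexity-entropy chain preprocessing: 40 Hz lowpass + resample to 1 kHz
#'
#' Denoises with a zero-phase Butterworth lowpass (default 40 Hz, order 4)
#' and then keeps every k-th sample to reach the target rate (default
#' 1 kHz). The input rate must be an integer multiple of the target rate;
#' an input already at the target rate is lowpassed only.
#'
#' @inheritParams bandpass_spike
#' @param lowpass_order Butterworth order of the denoising lowpass.
#' @return a [raw_recording()] at `config$ce_rate_hz`.
#' @export
ce_preprocess <- function(rec, config = analysis_config(), lowpass_order = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  spec <- filter_spec("butterworth-lowpass", order = lowpass_order,
                      band = config$ce_lowpass_hz)
  decimate_rec(apply_filter(rec, spec), config$ce_rate_hz)
}

#' Prediction-chain preprocessing: 300 Hz lowpass + resample to 250 Hz
#'
#' Applies the 5th-order Butterworth lowpass at 300 Hz (zero-phase) that
#' removes noise while keeping spike deflections, then keeps every k-th
#' sample to reach 250 Hz, i.e. one sample per 4 ms. DC is preserved
#' (lowpass, not bandpass).
#'
#' @inheritParams bandpass_spike
#' @return a [raw_recording()] at `config$predict_rate_hz`.
#' @export
predict_preprocess <- function(rec, config = analysis_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  spec <- filter_spec("butterworth-lowpass", order = config$predict_filter_order,
                      band = config$predict_lowpass_hz)
  decimate_rec(apply_filter(rec, spec), config$predict_rate_hz)
}
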