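#' Spike train container
#'
#' Per-channel detected spikes: times (seconds, absolute), polarity, peak
#' amplitude and peak sample index. Usually produced by [detect_spikes()];
#' the constructor is exported so spike trains from other sources (or
#' synthetic fixtures) can enter the burst/metrics stages.
#'
#' @param channels named list (one element per channel) of data frames with
#'   columns `time` (s, sorted strictly increasing), `polarity` (+1/-1),
#'   `amplitude` (microvolts), `sample_index` (0-based, optional).
#' @param window_s length of the analysis window the spikes came from, s.
#' @param sampling_rate sampling rate of the source recording, Hz.
#' @param t0 start time of the analysis window, s.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(channels, window_s, sampling_rate = NA_real_, t0 = 0) {
  stopifnot(is.list(channels), !is.null(names(channels)), window_s > 0)
  for (nm in names(channels)) {
    df <- channels[[nm]]
    if (!is.data.frame(df) || !all(c("time", "polarity", "amplitude") %in% names(df)))
      stop("each channel needs columns time, polarity, amplitude")
    if (is.unsorted(df$time, strictly = TRUE) && nrow(df) > 1)
      stop("spike times must be strictly increasing (channel ", nm, ")")
  }
  structure(list(channels = channels, window_s = window_s,
                 sampling_rate = sampling_rate, t0 = t0),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- vapply(x$channels, nrow, integer(1))
  cat(sprintf("<spike_train> %d channels, %d spikes over %g s\n",
              length(n), sum(n), x$window_s))
  invisible(x)
}

#' Total spike count of a spike train
#' @param spikes a [spike_train()].
#' @return integer.
#' @export
n_spikes <- function(spikes) {
  sum(vapply(spikes$channels, nrow, integer(1)))
}

#' Threshold spike detection
#'
#' Detects positive and negative spikes on a bandpass-filtered recording as
#' excursions beyond `+/- k * sigma`, where `sigma` is the standard
#' deviation of each channel's filtered signal over the analysis window.
#' Each contiguous supra-threshold excursion yields one spike at its
#' extremum sample; events closer than the dead time are merged, keeping
#' the larger-amplitude one. Polarity is the sign of the extremum.
#'
#' @param filtered a [raw_recording()] already passed through
#'   [bandpass_spike()].
#' @param k threshold in multiples of sigma (default 5).
#' @param dead_time_ms minimum separation between spikes, ms (default 2 ms,
#'   the absolute refractory period, so multiphasic afterwaves are not
#'   double-counted).
#' @param sigma_method `"sd"` (plain standard deviation, the default) or
#'   `"mad"` (median-based robust estimate `median(|x|) / 0.6745`).
#' @return a [spike_train()] with one entry per channel.
#' @export
detect_spikes <- function(filtered, k = 5, dead_time_ms = 2,
                          sigma_method = c("sd", "mad")) {
  stopifnot(inherits(filtered, "raw_recording"))
  sigma_method <- match.arg(sigma_method)
  rate <- filtered$sampling_rate
  dead <- dead_time_ms / 1000
  out <- vector("list", nrow(filtered$data))
  names(out) <- filtered$channel_ids

  for (ch in seq_len(nrow(filtered$data))) {
    x <- filtered$data[ch, ]
    sigma <- if (sigma_method == "sd") stats::sd(x)
             else stats::median(abs(x)) / 0.6745
    if (!is.finite(sigma) || sigma == 0)
      stop("degenerate input: channel ", filtered$channel_ids[ch],
           " has zero variance")
    thr <- k * sigma
    above <- abs(x) > thr
    if (!any(above)) {
      out[[ch]] <- data.frame(time = numeric(0), polarity = integer(0),
                              amplitude = numeric(0), sample_index = integer(0))
      next
    }
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    cand_idx <- integer(length(runs))
    for (i in seq_along(runs)) {
      s <- starts[runs[i]]; e <- ends[runs[i]]
      seg <- x[s:e]
      cand_idx[i] <- s + which.max(abs(seg)) - 1L
    }
    amp <- x[cand_idx]
    tms <- filtered$t0 + (cand_idx - 1L) / rate
    # merge events within the dead time, keep the larger-amplitude one
    keep_i <- integer(0)
    for (i in seq_along(cand_idx)) {
      if (length(keep_i) > 0 && tms[i] - tms[keep_i[length(keep_i)]] < dead) {
        j <- keep_i[length(keep_i)]
        if (abs(amp[i]) > abs(amp[j])) keep_i[length(keep_i)] <- i
      } else {
        keep_i <- c(keep_i, i)
      }
    }
    out[[ch]] <- data.frame(time = tms[keep_i],
                            polarity = as.integer(sign(amp[keep_i])),
                            amplitude = amp[keep_i],
                            sample_index = cand_idx[keep_i] - 1L)
  }
  spike_train(out, window_s = rec_duration(filtered),
              sampling_rate = rate, t0 = filtered$t0)
}
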