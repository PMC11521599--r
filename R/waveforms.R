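#' Extract spike cutouts from a filtered recording
#'
#' One cutout per detected spike: the voltage window from 1 ms before to
#' 2 ms after the spike's peak sample. Spikes whose window would cross a
#' recording boundary are skipped and counted.
#'
#' @param filtered the [bandpass_spike()]-filtered [raw_recording()] the
#'   spikes were detected on.
#' @param spikes a [detect_spikes()] result.
#' @param pre_ms,post_ms window extent around the peak, ms.
#' @return object of class `spike_cutouts`: list with `waveforms` (n x
#'   samples matrix), `channel`, `time`, `sampling_rate`, `pre_ms`,
#'   `post_ms`, `n_boundary_skipped`.
#' @export
extract_cutouts <- function(filtered, spikes, pre_ms = 1, post_ms = 2) {
  stopifnot(inherits(filtered, "raw_recording"), inherits(spikes, "spike_train"))
  rate <- filtered$sampling_rate
  lay <- cutout_layout(rate, pre_ms, post_ms)
  n_samp <- ncol(filtered$data)
  rows <- list(); ch_out <- character(0); t_out <- numeric(0)
  skipped <- 0L
  for (ch in seq_len(nrow(filtered$data))) {
    df <- spikes$channels[[filtered$channel_ids[ch]]]
    if (is.null(df) || nrow(df) == 0) next
    for (i in seq_len(nrow(df))) {
      peak <- if (!is.null(df$sample_index))
        df$sample_index[i] + 1L
      else round((df$time[i] - filtered$t0) * rate) + 1L
      lo <- peak - lay$pre; hi <- peak + lay$post
      if (lo < 1L || hi > n_samp) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- filtered$data[ch, lo:hi]
      ch_out <- c(ch_out, filtered$channel_ids[ch])
      t_out <- c(t_out, df$time[i])
    }
  }
  waveforms <- if (length(rows)) do.call(rbind, rows)
               else matrix(numeric(0), 0, lay$length)
  structure(list(waveforms = waveforms, channel = ch_out, time = t_out,
                 sampling_rate = rate, pre_ms = pre_ms, post_ms = post_ms,
                 n_boundary_skipped = skipped),
            class = "spike_cutouts")
}

#' @export
print.spike_cutouts <- function(x, ...) {
  cat(sprintf("<spike_cutouts> %d cutouts of %d samples @ %g Hz (%d boundary-skipped)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$sampling_rate,
              x$n_boundary_skipped))
  invisible(x)
}

#' Cluster spike cutouts by waveform similarity
#'
#' k-means on energy-normalized (unit L2 norm) cutouts, with k selected by
#' the average silhouette width over `k = 2..k_max` (computed on a random
#' subsample when there are many cutouts); a single cluster is returned
#' when the best silhouette falls below `silhouette_min` or the cutouts are
#' (nearly) identical. Deterministic under `seed`.
#'
#' @param cutouts a [extract_cutouts()] result (or any `spike_cutouts`).
#' @param k_max maximum number of clusters to consider.
#' @param silhouette_min silhouette width below which one cluster is assumed.
#' @param seed integer seed.
#' @param max_silhouette_n subsample size for silhouette evaluation.
#' @return integer vector of cluster labels (one per cutout), with
#'   attribute `k`.
#' @export
cluster_cutouts <- function(cutouts, k_max = 6, silhouette_min = 0.2,
                            seed = 1L, max_silhouette_n = 500) {
  stopifnot(inherits(cutouts, "spike_cutouts"))
  w <- cutouts$waveforms
  n <- nrow(w)
  if (n == 0) stop("no cutouts to cluster")
  if (n == 1) return(structure(1L, k = 1L))
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  wn <- w / nrm
  # (nearly) identical cutouts: single cluster
  if (max(apply(wn, 2, stats::sd)) < 1e-10)
    return(structure(rep(1L, n), k = 1L))

  ks <- 2:min(k_max, n - 1)
  set.seed(stage_seed(seed, "cluster-subsample"))
  sub <- if (n > max_silhouette_n) sample.int(n, max_silhouette_n) else seq_len(n)
  d_sub <- stats::dist(wn[sub, , drop = FALSE])
  best_k <- 1L; best_sil <- -Inf
  fits <- list()
  for (k in ks) {
    set.seed(stage_seed(seed, "cluster-kmeans", k))
    fit <- tryCatch(stats::kmeans(wn, centers = k, nstart = 5, iter.max = 50),
                    error = function(e) NULL)
    if (is.null(fit)) next
    fits[[as.character(k)]] <- fit
    sil <- cluster::silhouette(fit$cluster[sub], d_sub)
    avg <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else NA_real_
    if (is.finite(avg) && avg > best_sil) {
      best_sil <- avg; best_k <- k
    }
  }
  if (best_k == 1L || best_sil < silhouette_min)
    return(structure(rep(1L, n), k = 1L))
  structure(as.integer(fits[[as.character(best_k)]]$cluster), k = best_k)
}

#' Average waveform of a cluster
#'
#' Pointwise mean of the selected cutouts.
#'
#' @param x a numeric matrix (cutouts in rows), a `spike_cutouts` object,
#'   or a list of `spike_cutouts` objects (which must share one sampling
#'   rate).
#' @param indices optional row selection.
#' @return numeric vector (the averaged cutout).
#' @export
average_waveform <- function(x, indices = NULL) {
  if (is.list(x) && !inherits(x, "spike_cutouts") && !is.data.frame(x)) {
    rates <- vapply(x, function(ci) ci$sampling_rate, numeric(1))
    if (length(unique(rates)) != 1)
      stop("mixed sampling rates across cutout sets")
    x <- do.call(rbind, lapply(x, `[[`, "waveforms"))
  } else if (inherits(x, "spike_cutouts")) {
    x <- x$waveforms
  }
  stopifnot(is.matrix(x), nrow(x) >= 1)
  if (!is.null(indices)) x <- x[indices, , drop = FALSE]
  if (nrow(x) == 0) stop("empty cluster")
  colMeans(x)
}

#' Waveform features of an averaged spike cutout
#'
#' Implements the five shape features on the 1 ms pre / 2 ms post window:
#' the baseline (mean of the first and last samples), the signed spike
#' amplitude (baseline to peak, peak at the 1 ms offset), the 1st
#' peak-to-trough ratio (absolute ratio of the opposite-sign extremum
#' before the peak to the peak amplitude), the amplitude slope
#' `(peak - 1st peak) / (t_peak - t_1st)` in microvolts/ms, the
#' peak-to-peak time (1st peak before to 2nd peak after, ms) and the spike
#' duration (peak to 2nd peak, ms). The 2nd peak is the first opposite-sign
#' local extremum after the peak with prominence at least
#' `second_peak_prominence` of the main amplitude; when absent, the spike
#' duration is measured to the window end and flagged.
#'
#' @param avg numeric vector, an averaged cutout.
#' @param sampling_rate sampling rate in Hz.
#' @param pre_ms pre-peak window extent, ms (locates the peak sample).
#' @param thresholds classifier threshold list, see [analysis_config()];
#'   `second_peak_prominence`, `cs_prominence` and `cs_min_separation_ms`
#'   are used here.
#' @return list of class `waveform_features`: `spike_amplitude`,
#'   `first_peak_trough_ratio`, `amplitude_slope`, `peak_to_peak_time`,
#'   `spike_duration`, `baseline`, plus auxiliaries `post_peak_ratio`,
#'   `n_negative_troughs`, `second_peak_missing`.
#' @export
compute_features <- function(avg, sampling_rate, pre_ms = 1,
                             thresholds = analysis_config()$waveform_thresholds) {
  stopifnot(is.numeric(avg), length(avg) >= 5)
  if (max(avg) - min(avg) < .Machine$double.eps * 100)
    stop("degenerate input: flat waveform")
  rate <- sampling_rate
  peak_i <- round(pre_ms / 1000 * rate) + 1L
  stopifnot(peak_i >= 2, peak_i < length(avg))
  t_ms <- (seq_along(avg) - peak_i) / rate * 1000

  baseline <- (avg[1] + avg[length(avg)]) / 2
  v <- avg - baseline
  amp <- v[peak_i]
  negative <- amp < 0
  sgn <- if (negative) 1 else -1   # opposite-sign extrema: +1 looks for maxima

  # 1st peak: opposite-sign extremum in the pre-peak window
  pre_seg <- v[1:(peak_i - 1L)]
  first_i <- if (negative) which.max(pre_seg) else which.min(pre_seg)
  first_amp <- pre_seg[first_i]
  ratio <- abs(first_amp / amp)
  slope <- (amp - first_amp) / (t_ms[peak_i] - t_ms[first_i])

  # 2nd peak: first opposite-sign local extremum after the peak with
  # prominence >= second_peak_prominence * |amp|
  post <- v[(peak_i + 1L):length(v)]
  oriented <- if (negative) post else -post
  loc <- which(diff(sign(diff(c(-Inf, oriented, -Inf)))) == -2)
  loc <- loc[oriented[loc] >= thresholds$second_peak_prominence * abs(amp)]
  second_missing <- length(loc) == 0
  second_i <- if (second_missing) length(v) else peak_i + loc[1]
  spike_duration <- t_ms[second_i] - t_ms[peak_i]
  peak_to_peak <- t_ms[second_i] - t_ms[first_i]

  # distinct troughs on the spike's own side (prominence and separation
  # thresholds), used by the compound-spike rule
  side <- if (negative) -v else v
  tr <- which(diff(sign(diff(c(-Inf, side, -Inf)))) == -2)
  tr <- tr[side[tr] >= thresholds$cs_prominence * abs(amp)]
  if (length(tr) > 1) {
    sep <- thresholds$cs_min_separation_ms
    kept <- tr[1]
    for (i in tr[-1]) if ((t_ms[i] - t_ms[kept[length(kept)]]) >= sep)
      kept <- c(kept, i)
    tr <- kept
  }

  structure(list(
    spike_amplitude = amp,
    first_peak_trough_ratio = ratio,
    amplitude_slope = slope,
    peak_to_peak_time = peak_to_peak,
    spike_duration = spike_duration,
    baseline = baseline,
    post_peak_ratio = abs(v[second_i] / amp) * !second_missing,
    n_negative_troughs = length(tr),
    second_peak_missing = second_missing),
    class = "waveform_features")
}

#' Classify an averaged waveform into RS/FS/TS/CS/PS
#'
#' Positive spikes (`spike_amplitude > 0`) are PS. Negative spikes are
#' routed through a decision tree: compound (CS) when at least two distinct
#' troughs of sufficient prominence exist; else triphasic (TS) when both
#' the pre- and post-peak positive phases reach the triphasic prominence
#' ratio; else fast spiking (FS) when the spike duration is below
#' `fs_max_duration_ms`; else regular spiking (RS). All negative-branch
#' criteria are ratios or durations, so the classification is invariant to
#' uniform amplitude scaling.
#'
#' @param features a [compute_features()] result.
#' @param thresholds classifier thresholds (see [analysis_config()]):
#'   `fs_max_duration_ms`, `triphasic_ratio`, `cs_prominence`,
#'   `cs_min_separation_ms`.
#' @return one of `"RS"`, `"FS"`, `"TS"`, `"CS"`, `"PS"`.
#' @export
classify_waveform <- function(features,
                              thresholds = analysis_config()$waveform_thresholds) {
  stopifnot(inherits(features, "waveform_features"))
  if (features$spike_amplitude > 0) return("PS")
  if (features$n_negative_troughs >= 2) return("CS")
  if (features$first_peak_trough_ratio >= thresholds$triphasic_ratio &&
      features$post_peak_ratio >= thresholds$triphasic_ratio) return("TS")
  if (features$spike_duration < thresholds$fs_max_duration_ms) return("FS")
  "RS"
}

#' Cluster, average and classify all cutouts of a recording
#'
#' Convenience wrapper running [cluster_cutouts()] per channel,
#' [average_waveform()] per cluster, then [compute_features()] and
#' [classify_waveform()].
#'
#' @param cutouts an [extract_cutouts()] result.
#' @param config an [analysis_config()].
#' @return data frame with one row per cluster: `channel`, `cluster`,
#'   `n_spikes`, `class` and the five features.
#' @export
classify_cutouts <- function(cutouts, config = analysis_config()) {
  stopifnot(inherits(cutouts, "spike_cutouts"))
  thr <- config$waveform_thresholds
  out <- list()
  chs <- unique(cutouts$channel)
  for (ci in seq_along(chs)) {
    ch <- chs[ci]
    idx <- which(cutouts$channel == ch)
    sub <- cutouts
    sub$waveforms <- cutouts$waveforms[idx, , drop = FALSE]
    sub$channel <- cutouts$channel[idx]
    sub$time <- cutouts$time[idx]
    labels <- cluster_cutouts(sub, seed = stage_seed(config$seed, "cluster", ci))
    for (cl in sort(unique(labels))) {
      avg <- average_waveform(sub$waveforms, which(labels == cl))
      f <- tryCatch(compute_features(avg, cutouts$sampling_rate,
                                     pre_ms = cutouts$pre_ms,
                                     thresholds = thr),
                    error = function(e) NULL)
      if (is.null(f)) next
      out[[length(out) + 1L]] <- data.frame(
        channel = ch, cluster = cl, n_spikes = sum(labels == cl),
        class = classify_waveform(f, thr),
        spike_amplitude = f$spike_amplitude,
        first_peak_trough_ratio = f$first_peak_trough_ratio,
        amplitude_slope = f$amplitude_slope,
        peak_to_peak_time = f$peak_to_peak_time,
        spike_duration = f$spike_duration,
        baseline = f$baseline,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(channel = character(0), cluster = integer(0),
                      n_spikes = integer(0), class = character(0)))
  do.call(rbind, out)
}

#' Waveform class prevalence
#'
#' Percentage of (clustered, averaged) waveforms per shape class.
#'
#' @param classes character vector of classes, or a [classify_cutouts()]
#'   data frame.
#' @return data frame `class`, `count`, `percent` (percentages sum to 100);
#'   zero rows with a warning when no waveform was classified.
#' @export
waveform_prevalence <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  lv <- c("RS", "FS", "TS", "CS", "PS")
  if (length(classes) == 0) {
    warning("no classified waveforms")
    return(data.frame(class = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  counts <- table(factor(classes, levels = lv))
  data.frame(class = lv, count = as.integer(counts),
             percent = 100 * as.numeric(counts) / length(classes))
}
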