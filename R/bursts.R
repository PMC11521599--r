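#' Network-wide cumulative-moving-average (CMA) burst detection
#'
#' Pools inter-spike intervals (ISIs) across all channels, builds an ISI
#' histogram (fixed bin width, ISIs above the cap clamped into the last,
#' overflow, bin), computes the cumulative moving average of the histogram
#' counts, and sets the burst ISI threshold at the bin where the CMA curve
#' has fallen to `alpha1 * max(CMA)` beyond its maximum. `alpha1` is chosen
#' from the skewness of the CMA curve using the published map of the CMA
#' method (skewness < 1: 1.0; < 4: 0.7; < 9: 0.5; else 0.3). Consecutive
#' spikes with ISI at or below the threshold are grouped per channel into
#' bursts of at least `min_spikes` spikes.
#'
#' When the pooled ISI histogram occupies a single bin (e.g. a perfectly
#' regular train) the threshold is undefined and an empty burst set is
#' returned — the documented convention.
#'
#' @param spikes a [spike_train()].
#' @param bin_ms histogram bin width, ms.
#' @param max_isi_ms histogram cap, ms (larger ISIs fall in the overflow bin).
#' @param min_spikes minimum number of spikes per burst.
#' @return object of class `burst_set`: list with `channels` (per-channel
#'   data frames `start`, `end`, `n_spikes`), `isi_threshold_ms`, and
#'   `diagnostics` (histogram, CMA curve, skewness, alpha1).
#' @export
cma_burst_detect <- function(spikes, bin_ms = 5, max_isi_ms = 1000,
                             min_spikes = 3) {
  stopifnot(inherits(spikes, "spike_train"), bin_ms > 0, min_spikes >= 1)
  empty <- function(reason, diag = NULL) {
    ch <- lapply(spikes$channels, function(df)
      data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0)))
    warning("no bursts detected: ", reason)
    structure(list(channels = ch, isi_threshold_ms = NA_real_,
                   diagnostics = diag),
              class = "burst_set")
  }

  isi_ms <- unlist(lapply(spikes$channels, function(df)
    if (nrow(df) >= 2) diff(df$time) * 1000 else numeric(0)),
    use.names = FALSE)
  if (length(isi_ms) < 1 || n_spikes(spikes) < 2)
    return(empty("fewer than two spikes network-wide"))

  breaks <- seq(0, max_isi_ms, by = bin_ms)
  counts <- graphics::hist(pmin(isi_ms, max_isi_ms), breaks = breaks,
                           plot = FALSE, right = TRUE)$counts
  if (sum(counts > 0) < 2)
    return(empty("pooled ISI histogram occupies a single bin",
                 list(histogram = counts)))

  cma <- cumsum(counts) / seq_along(counts)
  kmax <- which.max(cma)
  m <- mean(cma); s <- stats::sd(cma)
  skew <- if (s > 0) mean((cma - m)^3) / s^3 else 0
  alpha1 <- if (skew < 1) 1.0 else if (skew < 4) 0.7 else if (skew < 9) 0.5 else 0.3

  after <- which(seq_along(cma) >= kmax & cma < alpha1 * cma[kmax])
  kth <- if (length(after) > 0) after[1] - 1L else kmax
  kth <- max(kth, kmax)
  isi_threshold_ms <- breaks[kth + 1L]   # upper edge of the threshold bin

  ch_bursts <- lapply(spikes$channels, function(df) {
    nt <- nrow(df)
    if (nt < min_spikes)
      return(data.frame(start = numeric(0), end = numeric(0),
                        n_spikes = integer(0)))
    gaps_ok <- diff(df$time) * 1000 <= isi_threshold_ms
    # runs of consecutive short gaps; a run of g gaps holds g + 1 spikes
    r <- rle(gaps_ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    rows <- which(r$values & r$lengths + 1L >= min_spikes)
    if (!length(rows))
      return(data.frame(start = numeric(0), end = numeric(0),
                        n_spikes = integer(0)))
    data.frame(start = df$time[starts[rows]],
               end = df$time[ends[rows] + 1L],
               n_spikes = r$lengths[rows] + 1L)
  })

  structure(list(channels = ch_bursts,
                 isi_threshold_ms = isi_threshold_ms,
                 diagnostics = list(histogram = counts, breaks = breaks,
                                    cma = cma, skewness = skew,
                                    alpha1 = alpha1, cma_max_bin = kmax)),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  n <- vapply(x$channels, nrow, integer(1))
  cat(sprintf("<burst_set> %d bursts on %d channels, ISI threshold %.1f ms\n",
              sum(n), length(n), x$isi_threshold_ms))
  invisible(x)
}

#' Activity metrics per channel and network-pooled
#'
#' Spike rate (SR, Hz), burst rate (BR, Hz), burst durations (BD, ms),
#' percentage of spikes inside burst intervals, inter-spike intervals (ISI,
#' ms) and inter-burst intervals (IBI, ms; gap between consecutive burst
#' end and start), per channel and pooled over the network.
#'
#' @param spikes a [spike_train()].
#' @param bursts a [cma_burst_detect()] result on the same spikes.
#' @param window_s analysis window length in seconds; defaults to the spike
#'   train's window.
#' @return list with `per_channel` (data frame), `network` (one-row data
#'   frame), and pooled vectors `isi_ms`, `ibi_ms`, `bd_ms`.
#' @export
activity_metrics <- function(spikes, bursts, window_s = spikes$window_s) {
  stopifnot(inherits(spikes, "spike_train"), inherits(bursts, "burst_set"),
            window_s > 0)
  per <- lapply(names(spikes$channels), function(nm) {
    df <- spikes$channels[[nm]]
    bu <- bursts$channels[[nm]]
    nsp <- nrow(df); nb <- nrow(bu)
    isi <- if (nsp >= 2) diff(df$time) * 1000 else numeric(0)
    bd <- if (nb > 0) (bu$end - bu$start) * 1000 else numeric(0)
    ibi <- if (nb >= 2) (bu$start[-1] - bu$end[-nb]) * 1000 else numeric(0)
    inb <- if (nsp > 0 && nb > 0)
      sum(vapply(df$time, function(t)
        any(t >= bu$start & t <= bu$end), logical(1)))
    else 0L
    list(row = data.frame(
           channel = nm, n_spikes = nsp, sr_hz = nsp / window_s,
           n_bursts = nb, br_hz = nb / window_s,
           mean_bd_ms = if (nb > 0) mean(bd) else NA_real_,
           pct_spikes_in_burst = if (nsp > 0) 100 * inb / nsp else NA_real_,
           mean_isi_ms = if (length(isi)) mean(isi) else NA_real_,
           mean_ibi_ms = if (length(ibi)) mean(ibi) else NA_real_,
           stringsAsFactors = FALSE),
         isi = isi, ibi = ibi, bd = bd, inb = inb)
  })
  per_channel <- do.call(rbind, lapply(per, `[[`, "row"))
  tot_sp <- sum(per_channel$n_spikes)
  tot_b <- sum(per_channel$n_bursts)
  tot_inb <- sum(vapply(per, `[[`, numeric(1), "inb"))
  isi_ms <- unlist(lapply(per, `[[`, "isi"), use.names = FALSE)
  ibi_ms <- unlist(lapply(per, `[[`, "ibi"), use.names = FALSE)
  bd_ms <- unlist(lapply(per, `[[`, "bd"), use.names = FALSE)
  network <- data.frame(
    n_spikes = tot_sp, sr_hz = tot_sp / window_s,
    mean_channel_sr_hz = mean(per_channel$sr_hz),
    n_bursts = tot_b, br_hz = tot_b / window_s,
    mean_channel_br_hz = mean(per_channel$br_hz),
    mean_bd_ms = if (length(bd_ms)) mean(bd_ms) else NA_real_,
    pct_spikes_in_burst = if (tot_sp > 0) 100 * tot_inb / tot_sp else NA_real_,
    mean_isi_ms = if (length(isi_ms)) mean(isi_ms) else NA_real_,
    mean_ibi_ms = if (length(ibi_ms)) mean(ibi_ms) else NA_real_)
  list(per_channel = per_channel, network = network,
       isi_ms = isi_ms, ibi_ms = ibi_ms, bd_ms = bd_ms)
}
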