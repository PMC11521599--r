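#' Run the full analysis pipeline on one recording
#'
#' Slices the analysis window, then runs the three preprocessing chains and
#' their downstream stages: spike detection + CMA burst analysis + activity
#' metrics; ordinal complexity-entropy plane (optionally with the iAAFT
#' surrogate Kolmogorov-Smirnov test); waveform cutout classification and
#' prevalence; and random-forest predictability. Stages can be switched off
#' for partial runs.
#'
#' @param rec a [raw_recording()].
#' @param config an [analysis_config()]; its `analysis_window` is clipped
#'   to the recording extent.
#' @param stages character subset of
#'   `c("activity", "ce", "surrogate", "waveforms", "predict")`.
#' @return named list of result tables: `activity_per_channel`,
#'   `activity_network`, `ce_plane`, `surrogate_ks`, `surrogate_ce`,
#'   `waveform_classes`, `waveform_prevalence`, `prediction`, plus
#'   `objects` (the intermediate S3 objects).
#' @export
run_pipeline <- function(rec, config = analysis_config(),
                         stages = c("activity", "ce", "surrogate",
                                    "waveforms", "predict")) {
  stopifnot(inherits(rec, "raw_recording"))
  stages <- match.arg(stages, several.ok = TRUE)
  w <- config$analysis_window
  w[1] <- max(w[1], rec$t0)
  w[2] <- min(w[2], rec$t0 + rec_duration(rec))
  win <- slice_window(rec, w[1], w[2])

  out <- list(objects = list(window = c(start = w[1], end = w[2])))

  if (any(c("activity", "waveforms") %in% stages)) {
    filtered <- bandpass_spike(win, config)
    spikes <- detect_spikes(filtered, k = config$spike_threshold_k,
                            dead_time_ms = config$spike_dead_time_ms)
    out$objects$spikes <- spikes
    if ("activity" %in% stages) {
      bursts <- withCallingHandlers(
        cma_burst_detect(spikes, bin_ms = config$burst_bin_ms,
                         max_isi_ms = config$burst_max_isi_ms,
                         min_spikes = config$burst_min_spikes),
        warning = function(w_) invokeRestart("muffleWarning"))
      met <- activity_metrics(spikes, bursts)
      out$objects$bursts <- bursts
      out$activity_per_channel <- met$per_channel
      out$activity_network <- met$network
    }
    if ("waveforms" %in% stages) {
      cut <- extract_cutouts(filtered, spikes,
                             pre_ms = config$cutout_pre_ms,
                             post_ms = config$cutout_post_ms)
      cls <- classify_cutouts(cut, config)
      out$objects$cutouts <- cut
      out$waveform_classes <- cls
      out$waveform_prevalence <- withCallingHandlers(
        waveform_prevalence(cls),
        warning = function(w_) invokeRestart("muffleWarning"))
    }
  }

  if (any(c("ce", "surrogate") %in% stages)) {
    ce_rec <- ce_preprocess(win, config)
    if ("surrogate" %in% stages) {
      st <- surrogate_ce_test(ce_rec, config)
      out$ce_plane <- st$original
      out$surrogate_ce <- st$surrogate
      out$surrogate_ks <- st$ks
      out$objects$surrogate_test <- st
    } else {
      out$ce_plane <- ce_plane(ce_rec, config)
    }
  }

  # prediction uses the whole series (70/30 contiguous split), not the window
  if ("predict" %in% stages) {
    pr <- predict_preprocess(rec, config)
    out$prediction <- predictability(pr, config)
  }

  out
}
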