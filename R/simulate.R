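#' Generator parameters for synthetic MEA recordings
#'
#' Defines the statistics of one simulated culture: homogeneous-Poisson
#' tonic spiking plus bursts (Poisson or jittered-periodic onsets, fixed
#' spikes-per-burst, fixed intra-burst inter-spike interval with jitter),
#' extracellular spike templates drawn from a class mixture, a burst-locked
#' slow local-field deflection, and additive white Gaussian electrode noise.
#'
#' Three condition presets emulate decreasing activity, burstiness and
#' stereotypy: `"patterned"` (dense, periodic bursts, identical templates
#' per channel, strong burst-locked slow deflections — the profile of pure
#' neuronal cultures), `"intermediate"`, and `"irregular"` (sparse Poisson
#' spiking, heterogeneous jittered templates, weak slow deflections — the
#' profile of astrocyte-rich co-cultures).
#'
#' @param condition `"patterned"`, `"intermediate"` or `"irregular"`.
#' @param n_channels number of electrodes.
#' @param duration_s recording length in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param noise_sd_uv electrode noise standard deviation, microvolts.
#' @param seed integer seed; every stochastic draw is derived from it.
#' @param ... overrides for individual preset fields (see Details).
#'
#' @details Preset fields (all overridable via `...`): `tonic_rate_hz`,
#' `burst_rate_hz`, `spikes_per_burst`, `intra_isi_ms`, `isi_jitter_ms`,
#' `burst_timing` (`"periodic"` or `"poisson"`), `onset_jitter_ms`,
#' `class_mix` (named probabilities over RS/FS/TS/CS/PS), `class_per`
#' (`"channel"` or `"spike"`), `spike_amplitude_uv` (positive; the sign is
#' set per class), `amplitude_jitter` (sd of the multiplicative amplitude
#' noise), `lfp_amplitude_uv` (burst-locked slow field deflection, 0
#' disables), `lfp_width_s` (its Gaussian width; population bursts in
#' cultured networks produce field deflections lasting hundreds of
#' milliseconds), `lfp_jitter`, `slow_osc_uv` and `slow_osc_hz` (an ongoing
#' slow population rhythm rendered as a truncated-sawtooth waveform — fast
#' rise, slow fall, harmonics phase-locked; this nonlinear phase structure
#' is what distinguishes patterned activity from its linear iAAFT
#' surrogates, 0 disables), and `refractory_ms`.
#'
#' @return list of class `generator_params`.
#' @export
generator_params <- function(condition = c("patterned", "intermediate", "irregular"),
                             n_channels = 60, duration_s = 300,
                             sampling_rate = 25000, noise_sd_uv = 10,
                             seed = 1L, ...) {
  condition <- match.arg(condition)
  preset <- switch(condition,
    patterned = list(
      tonic_rate_hz = 2.0, burst_rate_hz = 0.4, spikes_per_burst = 8,
      intra_isi_ms = 10, isi_jitter_ms = 0.3,
      burst_timing = "periodic", onset_jitter_ms = 20,
      class_mix = c(RS = 0.70, FS = 0.20, TS = 0.05, CS = 0.025, PS = 0.025),
      class_per = "channel",
      spike_amplitude_uv = 80, amplitude_jitter = 0.03,
      lfp_amplitude_uv = 40, lfp_width_s = 0.18, lfp_jitter = 0.05,
      slow_osc_uv = 15, slow_osc_hz = 1.5,
      refractory_ms = 2),
    intermediate = list(
      tonic_rate_hz = 1.5, burst_rate_hz = 0.25, spikes_per_burst = 6,
      intra_isi_ms = 15, isi_jitter_ms = 1.0,
      burst_timing = "poisson", onset_jitter_ms = 0,
      class_mix = c(RS = 0.50, FS = 0.20, TS = 0.15, CS = 0.10, PS = 0.05),
      class_per = "channel",
      spike_amplitude_uv = 70, amplitude_jitter = 0.10,
      lfp_amplitude_uv = 20, lfp_width_s = 0.12, lfp_jitter = 0.15,
      slow_osc_uv = 6, slow_osc_hz = 1.2,
      refractory_ms = 2),
    irregular = list(
      tonic_rate_hz = 0.8, burst_rate_hz = 0.05, spikes_per_burst = 4,
      intra_isi_ms = 25, isi_jitter_ms = 3.0,
      burst_timing = "poisson", onset_jitter_ms = 0,
      class_mix = c(RS = 0.20, FS = 0.20, TS = 0.20, CS = 0.20, PS = 0.20),
      class_per = "spike",
      spike_amplitude_uv = 60, amplitude_jitter = 0.30,
      lfp_amplitude_uv = 5, lfp_width_s = 0.10, lfp_jitter = 0.50,
      slow_osc_uv = 0, slow_osc_hz = 1.0,
      refractory_ms = 2)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(preset))
  if (length(unknown)) stop("unknown generator fields: ",
                            paste(unknown, collapse = ", "))
  preset[names(dots)] <- dots
  stopifnot(preset$tonic_rate_hz >= 0, preset$burst_rate_hz >= 0,
            noise_sd_uv > 0, duration_s > 0, n_channels >= 1,
            abs(sum(preset$class_mix) - 1) < 1e-9)
  structure(c(list(condition = condition, n_channels = n_channels,
                   duration_s = duration_s, sampling_rate = sampling_rate,
                   noise_sd_uv = noise_sd_uv, seed = as.integer(seed)),
              preset),
            class = "generator_params")
}

#' Generate one channel's spike times and burst intervals
#'
#' Homogeneous Poisson tonic spikes plus bursts whose onsets follow either a
#' Poisson process or a jittered periodic schedule; each burst holds a fixed
#' number of spikes at a fixed (jittered) intra-burst inter-spike interval.
#' An absolute refractory period is enforced greedily on the merged train.
#'
#' @param rate tonic spike rate, Hz.
#' @param burst_params list with `burst_rate_hz`, `spikes_per_burst`,
#'   `intra_isi_ms`, and optionally `isi_jitter_ms`, `burst_timing`,
#'   `onset_jitter_ms`.
#' @param duration duration in seconds.
#' @param refractory_ms absolute refractory period, ms.
#' @param seed integer seed.
#' @return list with `times` (sorted, s), `in_burst` (logical), `burst_id`
#'   (integer, `NA` for tonic spikes) and `bursts` (data frame `start`,
#'   `end`, `n_spikes`).
#' @export
generate_spike_times <- function(rate, burst_params = list(burst_rate_hz = 0),
                                 duration, refractory_ms = 2, seed = 1L) {
  stopifnot(duration > 0, rate >= 0)
  bp <- utils::modifyList(
    list(burst_rate_hz = 0, spikes_per_burst = 5, intra_isi_ms = 10,
         isi_jitter_ms = 0, burst_timing = "poisson", onset_jitter_ms = 0),
    burst_params)
  set.seed(seed)

  # burst onsets
  onsets <- numeric(0)
  if (bp$burst_rate_hz > 0) {
    if (identical(bp$burst_timing, "periodic")) {
      period <- 1 / bp$burst_rate_hz
      k <- floor(duration / period)
      if (k >= 1) {
        onsets <- (seq_len(k) - 0.5) * period +
          stats::rnorm(k, 0, bp$onset_jitter_ms / 1000)
        onsets <- sort(onsets[onsets >= 0 & onsets < duration])
      }
    } else {
      n <- stats::rpois(1, bp$burst_rate_hz * duration)
      onsets <- sort(stats::runif(n, 0, duration))
    }
  }

  times <- numeric(0); in_burst <- logical(0); burst_id <- integer(0)
  for (b in seq_along(onsets)) {
    gaps <- (bp$intra_isi_ms +
               stats::rnorm(bp$spikes_per_burst - 1, 0, bp$isi_jitter_ms)) / 1000
    gaps <- pmax(gaps, refractory_ms / 1000)
    ts <- onsets[b] + c(0, cumsum(gaps))
    ts <- ts[ts < duration]
    times <- c(times, ts)
    in_burst <- c(in_burst, rep(TRUE, length(ts)))
    burst_id <- c(burst_id, rep(b, length(ts)))
  }
  n_tonic <- stats::rpois(1, rate * duration)
  if (n_tonic > 0) {
    ts <- stats::runif(n_tonic, 0, duration)
    times <- c(times, ts)
    in_burst <- c(in_burst, rep(FALSE, n_tonic))
    burst_id <- c(burst_id, rep(NA_integer_, n_tonic))
  }

  o <- order(times)
  times <- times[o]; in_burst <- in_burst[o]; burst_id <- burst_id[o]
  # greedy refractory enforcement on the merged train
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_ms / 1000) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]; in_burst <- in_burst[keep]; burst_id <- burst_id[keep]

  ids <- sort(unique(burst_id[!is.na(burst_id)]))
  bursts <- do.call(rbind, lapply(ids, function(b) {
    ts <- times[!is.na(burst_id) & burst_id == b]
    data.frame(start = min(ts), end = max(ts), n_spikes = length(ts))
  }))
  if (is.null(bursts))
    bursts <- data.frame(start = numeric(0), end = numeric(0),
                         n_spikes = integer(0))
  list(times = times, in_burst = in_burst, burst_id = burst_id,
       bursts = bursts)
}

#' Render a synthetic MEA recording with ground truth
#'
#' For each channel independently: draws spike times and bursts with
#' [generate_spike_times()], inserts class-specific templates
#' ([make_waveform_template()]) with per-spike amplitude jitter, adds one
#' slow negative local-field deflection per burst (Gaussian bump spanning
#' the burst), and adds white Gaussian electrode noise. Channels receive
#' decoupled substreams of the global seed, so the output is fully
#' deterministic. Overlapping templates are summed.
#'
#' @param params a [generator_params()].
#' @return list with `recording` (a [raw_recording()]) and `ground_truth`:
#'   a list with per-channel elements `spike_times`, `classes`, `in_burst`,
#'   `bursts` (data frame), plus `n_insertions`.
#' @export
render_recording <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  rate <- params$sampling_rate
  n <- round(params$duration_s * rate)
  data <- matrix(0, nrow = params$n_channels, ncol = n)
  classes_all <- names(params$class_mix)
  lay <- cutout_layout(rate)
  gt <- vector("list", params$n_channels)
  n_insertions <- 0L

  for (ch in seq_len(params$n_channels)) {
    ch_seed <- stage_seed(params$seed, "simulate-spikes", ch)
    train <- generate_spike_times(
      rate = params$tonic_rate_hz,
      burst_params = params[c("burst_rate_hz", "spikes_per_burst",
                              "intra_isi_ms", "isi_jitter_ms",
                              "burst_timing", "onset_jitter_ms")],
      duration = params$duration_s,
      refractory_ms = params$refractory_ms,
      seed = ch_seed)

    set.seed(stage_seed(params$seed, "simulate-render", ch))
    x <- stats::rnorm(n, 0, params$noise_sd_uv)

    nsp <- length(train$times)
    if (nsp > 0) {
      if (identical(params$class_per, "channel")) {
        cls <- rep(sample(classes_all, 1, prob = params$class_mix), nsp)
      } else {
        cls <- sample(classes_all, nsp, replace = TRUE,
                      prob = params$class_mix)
      }
      amps <- params$spike_amplitude_uv *
        pmax(0.2, 1 + stats::rnorm(nsp, 0, params$amplitude_jitter))
      templates <- lapply(classes_all, function(cl)
        make_waveform_template(cl, if (cl == "PS") 1 else -1,
                               sampling_rate = rate))
      names(templates) <- classes_all
      for (i in seq_len(nsp)) {
        idx <- round(train$times[i] * rate) + 1L   # peak sample, 1-based
        lo <- idx - lay$pre; hi <- idx + lay$post
        tpl <- templates[[cls[i]]] * amps[i]
        s0 <- max(1L, lo); s1 <- min(n, hi)
        if (s1 >= s0) {
          x[s0:s1] <- x[s0:s1] + tpl[(s0 - lo + 1L):(s1 - lo + 1L)]
          n_insertions <- n_insertions + 1L
        }
      }
    } else {
      cls <- character(0)
    }

    # burst-locked slow local-field deflection
    if (params$lfp_amplitude_uv > 0 && nrow(train$bursts) > 0) {
      tgrid <- NULL
      for (b in seq_len(nrow(train$bursts))) {
        mid <- (train$bursts$start[b] + train$bursts$end[b]) / 2
        span <- max(train$bursts$end[b] - train$bursts$start[b], 0.04)
        sd_s <- max(span / 2, params$lfp_width_s)
        a <- params$lfp_amplitude_uv *
          max(0.1, 1 + stats::rnorm(1, 0, params$lfp_jitter))
        lo <- max(1L, floor((mid - 3 * sd_s) * rate) + 1L)
        hi <- min(n, ceiling((mid + 3 * sd_s) * rate) + 1L)
        if (hi > lo) {
          tt <- ((lo:hi) - 1) / rate
          x[lo:hi] <- x[lo:hi] - a * exp(-0.5 * ((tt - mid) / sd_s)^2)
        }
      }
    }

    # ongoing slow population rhythm: truncated sawtooth (first six
    # harmonics, phase-locked), per-channel random phase and slight
    # frequency detuning
    if (params$slow_osc_uv > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      f0 <- params$slow_osc_hz * (1 + stats::rnorm(1, 0, 0.02))
      th <- 2 * pi * f0 * ((seq_len(n) - 1) / rate) + phi
      osc <- numeric(n)
      for (k in 1:6) osc <- osc + sin(k * th) / k
      x <- x + params$slow_osc_uv * osc / 1.76  # peak of the 6-harmonic sum
    }

    data[ch, ] <- x
    gt[[ch]] <- list(spike_times = train$times, classes = cls,
                     in_burst = train$in_burst, bursts = train$bursts)
  }

  rec <- raw_recording(data, rate,
                       channel_ids = sprintf("ch%02d", seq_len(params$n_channels)))
  names(gt) <- rec$channel_ids
  list(recording = rec,
       ground_truth = list(channels = gt, n_insertions = n_insertions,
                           condition = params$condition,
                           seed = params$seed))
}
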