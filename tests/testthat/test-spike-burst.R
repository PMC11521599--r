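render_snr8 <- function(n_channels = 2, duration = 30, seed = 7) {
  render_recording(generator_params("patterned", n_channels = n_channels,
                                    duration_s = duration,
                                    sampling_rate = 25000, seed = seed))
}

test_that("threshold detection recovers ground-truth spikes at SNR 8", {
  r <- render_snr8()
  f <- bandpass_spike(r$recording)
  sp <- detect_spikes(f, k = 5)
  for (ch in seq_along(sp$channels)) {
    gt <- r$ground_truth$channels[[ch]]$spike_times
    det <- sp$channels[[ch]]$time
    hit <- vapply(gt, function(t) any(abs(det - t) <= 2e-4), logical(1))
    fp <- sum(vapply(det, function(t) all(abs(gt - t) > 2e-4), logical(1)))
    expect_gte(mean(hit), 0.95)
    expect_lte(fp, 5 * length(gt) / 200)
  }
})

test_that("detection degenerates and symmetries behave", {
  # all-zero channel: degenerate-input error
  z <- raw_recording(matrix(0, 1, 1000), 25000)
  expect_error(detect_spikes(z), "degenerate")

  # negated input: identical times, flipped polarities
  r <- render_snr8(n_channels = 1, duration = 10)
  f <- bandpass_spike(r$recording)
  sp <- detect_spikes(f)
  fneg <- raw_recording(-f$data, f$sampling_rate, f$channel_ids, f$t0)
  spn <- detect_spikes(fneg)
  expect_equal(spn$channels[[1]]$time, sp$channels[[1]]$time)
  expect_equal(spn$channels[[1]]$polarity, -sp$channels[[1]]$polarity)

  # DC offset before filtering does not change the detection count
  roff <- raw_recording(r$recording$data + 50, 25000)
  spo <- detect_spikes(bandpass_spike(roff))
  expect_equal(n_spikes(spo), n_spikes(sp))
})

test_that("metrics commute with window slicing", {
  r <- render_snr8(n_channels = 1, duration = 40, seed = 13)
  cfg <- analysis_config(analysis_window = c(10, 30))
  # filter whole recording, then detect on the slice
  f <- bandpass_spike(r$recording)
  spA <- detect_spikes(slice_window(f, 10, 30))
  # slice first, then filter and detect
  spB <- detect_spikes(bandpass_spike(slice_window(r$recording, 10, 30)))
  # same spikes up to filter edge effects: compare counts and rates
  expect_lt(abs(n_spikes(spA) - n_spikes(spB)), 3)
  mA <- activity_metrics(spA, suppressWarnings(cma_burst_detect(spA)))
  expect_equal(mA$per_channel$sr_hz, n_spikes(spA) / 20)
})

test_that("CMA burst detection resolves the 20-burst fixture", {
  st <- twenty_burst_train()
  bs <- cma_burst_detect(st, min_spikes = 3)
  expect_equal(sum(vapply(bs$channels, nrow, integer(1))), 20)
  expect_gt(bs$isi_threshold_ms, 10)
  expect_lt(bs$isi_threshold_ms, 2000)
  bd <- (bs$channels$ch01$end - bs$channels$ch01$start) * 1000
  expect_true(all(abs(bd - 40) < 1))
  # all member ISIs are at or below the threshold
  for (i in seq_len(nrow(bs$channels$ch01))) {
    inb <- st$channels$ch01$time[
      st$channels$ch01$time >= bs$channels$ch01$start[i] &
      st$channels$ch01$time <= bs$channels$ch01$end[i]]
    expect_true(all(diff(inb) * 1000 <= bs$isi_threshold_ms))
  }
})

test_that("degenerate trains yield empty burst sets by convention", {
  # perfectly regular train: single-bin ISI histogram -> 0 bursts
  reg <- spike_train(list(ch01 = data.frame(time = seq(0.1, 99.9, by = 0.1),
                                            polarity = -1L, amplitude = -50)),
                     window_s = 100)
  expect_warning(b <- cma_burst_detect(reg), "single bin")
  expect_equal(sum(vapply(b$channels, nrow, integer(1))), 0)

  # empty / near-empty train
  one <- spike_train(list(ch01 = data.frame(time = 1, polarity = -1L,
                                            amplitude = -50)), window_s = 100)
  expect_warning(b1 <- cma_burst_detect(one), "fewer than two")
  expect_equal(sum(vapply(b1$channels, nrow, integer(1))), 0)
})

test_that("activity metrics match their definitions", {
  # 100 uniformly placed spikes in 100 s -> SR = 1 Hz
  uni <- spike_train(list(ch01 = data.frame(time = seq(0.5, 99.5, length.out = 100),
                                            polarity = -1L, amplitude = -50)),
                     window_s = 100)
  m <- activity_metrics(uni, suppressWarnings(cma_burst_detect(uni)))
  expect_equal(m$per_channel$sr_hz, 1)
  expect_equal(unique(round(m$isi_ms, 6)),
               round(99 / 99 * 1000, 6))  # all ISI equal

  # the 20-burst fixture: BR = 0.2 Hz, 100% spikes in bursts
  st <- twenty_burst_train()
  mb <- activity_metrics(st, cma_burst_detect(st))
  expect_equal(mb$per_channel$br_hz, 0.2)
  expect_equal(mb$per_channel$pct_spikes_in_burst, 100)
  expect_equal(length(mb$ibi_ms), 19)

  # zero spikes -> SR 0 and empty lists
  none <- spike_train(list(ch01 = data.frame(time = numeric(0),
                                             polarity = integer(0),
                                             amplitude = numeric(0))),
                      window_s = 100)
  m0 <- activity_metrics(none, suppressWarnings(cma_burst_detect(none)))
  expect_equal(m0$per_channel$sr_hz, 0)
  expect_length(m0$isi_ms, 0)
})

test_that("activity ordering across presets follows the generator", {
  sr <- vapply(c("patterned", "intermediate", "irregular"), function(cond) {
    p <- generator_params(cond, n_channels = 4, duration_s = 30,
                          sampling_rate = 25000, seed = 23)
    r <- render_recording(p)
    sp <- detect_spikes(bandpass_spike(r$recording))
    mean(vapply(sp$channels, nrow, integer(1))) / 30
  }, numeric(1))
  expect_true(sr["patterned"] > sr["intermediate"])
  expect_true(sr["intermediate"] > sr["irregular"])
})
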