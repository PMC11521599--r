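test_that("waveform templates honour their class geometry", {
  rate <- 25000
  lay <- cutout_layout(rate)
  for (cl in wf_classes) {
    amp <- if (cl == "PS") 30 else -50
    tpl <- make_waveform_template(cl, amp, sampling_rate = rate)
    expect_length(tpl, lay$length)
    extreme <- if (cl == "PS") max(tpl) else min(tpl)
    expect_equal(extreme, amp)
  }
  # TS phase extrema sign sequence is (+, -, +)
  ts <- make_waveform_template("TS", -50, sampling_rate = rate)
  pk <- lay$pre + 1L
  expect_gt(max(ts[1:(pk - 1)]), 5)              # prominent positive pre-phase
  expect_equal(which.min(ts), pk)
  expect_gt(max(ts[(pk + 1):length(ts)]), 5)     # prominent positive post-phase
  # CS has two distinct negative local minima
  cs <- make_waveform_template("CS", -50, sampling_rate = rate)
  mins <- which(diff(sign(diff(cs))) == 2) + 1L
  deep <- mins[cs[mins] < -15]
  expect_gte(length(deep), 2)
  # PS stays above the negative-phase scale
  ps <- make_waveform_template("PS", 30, sampling_rate = rate)
  expect_gt(min(ps), -0.3 * 30)
  # FS is narrower than RS (time from trough to positive afterwave peak)
  dur <- function(tpl) {
    pk <- which.min(tpl)
    (which.max(tpl[(pk + 1):length(tpl)])) / rate * 1000
  }
  expect_lt(dur(make_waveform_template("FS", -50, sampling_rate = rate)),
            dur(make_waveform_template("RS", -50, sampling_rate = rate)))
  expect_error(make_waveform_template("XX", -50), "unknown")
  expect_error(make_waveform_template("RS", 50), "negative")
  expect_error(make_waveform_template("PS", -50), "positive")
})

test_that("generate_spike_times matches its Poisson/burst construction", {
  # zero rates -> empty train
  z <- generate_spike_times(0, list(burst_rate_hz = 0), duration = 10, seed = 1)
  expect_length(z$times, 0)
  expect_equal(nrow(z$bursts), 0)

  # burst process: ~20 bursts of 5 spikes spanning ~40 ms each
  g <- generate_spike_times(0, list(burst_rate_hz = 0.2, spikes_per_burst = 5,
                                    intra_isi_ms = 10),
                            duration = 100, seed = 42)
  expect_lt(abs(nrow(g$bursts) - 20), 3 * sqrt(20) + 1)
  spans <- (g$bursts$end - g$bursts$start) * 1000
  expect_true(all(abs(spans - 40) < 1))
  expect_true(all(g$in_burst))

  # tonic rate recovered within 10%
  t10 <- generate_spike_times(10, list(burst_rate_hz = 0), duration = 300,
                              seed = 7)
  expect_lt(abs(length(t10$times) / 300 - 10) / 10, 0.1)

  # sorted times with refractory gaps
  expect_true(!is.unsorted(t10$times, strictly = TRUE))
  expect_true(all(diff(t10$times) >= 0.002 - 1e-12))

  # every in-burst spike lies inside a burst interval
  inb <- g$times[g$in_burst]
  ok <- vapply(inb, function(t)
    any(t >= g$bursts$start - 1e-12 & t <= g$bursts$end + 1e-12), logical(1))
  expect_true(all(ok))
})

test_that("render_recording is deterministic and keeps its books", {
  # zero rates -> pure noise, empty ground truth
  p0 <- generator_params("irregular", n_channels = 2, duration_s = 2,
                         sampling_rate = 5000, seed = 3,
                         tonic_rate_hz = 0, burst_rate_hz = 0)
  r0 <- render_recording(p0)
  expect_equal(r0$ground_truth$n_insertions, 0)
  expect_true(all(vapply(r0$ground_truth$channels,
                         function(g) length(g$spike_times), numeric(1)) == 0))
  expect_lt(abs(sd(r0$recording$data[1, ]) - 10), 1)

  # same params + same seed -> identical matrices
  p <- generator_params("patterned", n_channels = 3, duration_s = 5,
                        sampling_rate = 5000, seed = 9)
  r1 <- render_recording(p)
  r2 <- render_recording(p)
  expect_identical(r1$recording$data, r2$recording$data)

  # rendered insertions equal the total ground-truth spike count
  total <- sum(vapply(r1$ground_truth$channels,
                      function(g) length(g$spike_times), numeric(1)))
  expect_equal(r1$ground_truth$n_insertions, total)

  # condition presets are ordered in rate and burstiness
  rates <- vapply(c("patterned", "intermediate", "irregular"), function(cond) {
    pp <- generator_params(cond, n_channels = 4, duration_s = 30,
                           sampling_rate = 5000, seed = 5)
    rr <- render_recording(pp)
    sum(vapply(rr$ground_truth$channels,
               function(g) length(g$spike_times), numeric(1))) / 30 / 4
  }, numeric(1))
  expect_true(rates["patterned"] > rates["intermediate"])
  expect_true(rates["intermediate"] > rates["irregular"])
})
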