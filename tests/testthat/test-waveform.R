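test_that("cutout extraction centers the peak and skips boundary spikes", {
  r <- render_recording(generator_params("patterned", n_channels = 1,
                                         duration_s = 10,
                                         sampling_rate = 25000, seed = 17))
  f <- bandpass_spike(r$recording)
  sp <- detect_spikes(f)
  cut <- extract_cutouts(f, sp)
  lay <- cutout_layout(25000)
  expect_equal(ncol(cut$waveforms), lay$length)
  expect_equal(nrow(cut$waveforms) + cut$n_boundary_skipped, n_spikes(sp))
  # extremum sits at the 1 ms offset
  peaks <- apply(abs(cut$waveforms), 1, which.max)
  expect_true(all(peaks == lay$pre + 1L))

  # a spike 0.5 ms after recording start is skipped and counted
  fake <- sp
  fake$channels$ch01 <- rbind(
    data.frame(time = 0.0005, polarity = -1L, amplitude = -50,
               sample_index = round(0.0005 * 25000)),
    sp$channels$ch01)
  cut2 <- extract_cutouts(f, fake)
  expect_equal(cut2$n_boundary_skipped, cut$n_boundary_skipped + 1L)
})

test_that("clustering separates distinct templates and collapses duplicates", {
  t1 <- make_waveform_template("RS", -100, sampling_rate = 25000)
  t2 <- make_waveform_template("PS", 100, sampling_rate = 25000)
  w <- rbind(noisy_cutouts(t1, 60, 10, seed = 3),
             noisy_cutouts(t2, 60, 10, seed = 4))
  lab <- cluster_cutouts(as_cutouts(w), seed = 5)
  expect_equal(attr(lab, "k"), 2)
  truth <- rep(1:2, each = 60)
  purity <- sum(apply(table(lab, truth), 1, max)) / length(truth)
  expect_gte(purity, 0.95)
  # determinism under seed
  expect_identical(lab, cluster_cutouts(as_cutouts(w), seed = 5))

  # identical cutouts duplicated -> one cluster
  dup <- as_cutouts(matrix(rep(t1, each = 50), nrow = 50, byrow = FALSE))
  expect_equal(attr(cluster_cutouts(dup, seed = 1), "k"), 1)
  # single cutout -> single cluster
  one <- as_cutouts(matrix(t1, nrow = 1))
  expect_equal(attr(cluster_cutouts(one, seed = 1), "k"), 1)
})

test_that("average_waveform is the pointwise mean with rate checking", {
  x <- rnorm(76)
  expect_equal(average_waveform(rbind(x, -x)), rep(0, 76))
  expect_equal(average_waveform(matrix(x, nrow = 1)), x)
  expect_equal(average_waveform(rbind(x, x, x)), x)
  a <- as_cutouts(rbind(x, x), sampling_rate = 25000)
  b <- as_cutouts(rbind(x, x), sampling_rate = 12500)
  expect_error(average_waveform(list(a, b)), "mixed sampling rates")
})

test_that("features match the constructed-landmark example", {
  # baseline 0, 1st peak +10 at -0.4 ms, spike -50 at 0, 2nd peak +20 at +0.8 ms
  rate <- 25000
  lay <- cutout_layout(rate)
  t_ms <- ((seq_len(lay$length)) - (lay$pre + 1)) / rate * 1000
  w <- 10 * exp(-0.5 * ((t_ms + 0.4) / 0.07)^2) -
       50 * exp(-0.5 * (t_ms / 0.09)^2) +
       20 * exp(-0.5 * ((t_ms - 0.8) / 0.12)^2)
  n <- length(w)
  w <- w - (w[1] + (w[n] - w[1]) * (seq_len(n) - 1) / (n - 1))
  f <- compute_features(w, rate)
  expect_equal(f$baseline, 0)
  expect_equal(f$spike_amplitude, -50, tolerance = 1e-2)
  expect_equal(f$first_peak_trough_ratio, 10 / 50, tolerance = 1e-2)
  expect_equal(f$amplitude_slope, (-50 - 10) / 0.4, tolerance = 1e-2)
  expect_equal(f$peak_to_peak_time, 1.2, tolerance = 1e-2)
  expect_equal(f$spike_duration, 0.8, tolerance = 1e-2)

  # baseline from first/last samples
  w2 <- w; w2[1] <- w2[1] + 2; w2[length(w2)] <- w2[length(w2)] + 4
  expect_equal(compute_features(w2, rate)$baseline, 3)

  # no post-peak opposite extremum: duration to window end, flagged
  w3 <- -50 * exp(-0.5 * (pmin(t_ms, 0) / 0.12)^2)
  w3[t_ms > 0] <- seq(-50, -0.01, length.out = sum(t_ms > 0))
  f3 <- compute_features(w3, rate)
  expect_true(f3$second_peak_missing)
  expect_equal(f3$spike_duration, 2, tolerance = 0.01)

  expect_error(compute_features(rep(1, 76), rate), "flat")
})

test_that("classification recovers every noise-free template class", {
  thr <- analysis_config()$waveform_thresholds
  for (cl in wf_classes) {
    amp <- if (cl == "PS") 40 else -60
    tpl <- make_waveform_template(cl, amp, sampling_rate = 25000)
    f <- compute_features(tpl, 25000)
    expect_equal(abs(f$spike_amplitude - amp), 0, tolerance = 1e-9)
    expect_equal(classify_waveform(f, thr), cl)
  }
})

test_that("negative-branch classification is scale invariant", {
  thr <- analysis_config()$waveform_thresholds
  for (cl in c("RS", "FS", "TS", "CS")) {
    for (scale in c(0.2, 1, 5, 40)) {
      tpl <- make_waveform_template(cl, -10 * scale, sampling_rate = 25000)
      f <- compute_features(tpl, 25000)
      expect_equal(classify_waveform(f, thr), cl)
    }
  }
})

test_that("classifier reaches 90% accuracy on the noisy five-class mixture", {
  thr <- analysis_config()$waveform_thresholds
  acc <- vapply(1:10, function(sd0) {
    ok <- 0
    for (cl in wf_classes) {
      amp <- if (cl == "PS") 80 else -80
      tpl <- make_waveform_template(cl, amp, sampling_rate = 25000)
      w <- noisy_cutouts(tpl, 40, 10, seed = stage_seed(sd0, "mix", match(cl, wf_classes)))
      f <- compute_features(average_waveform(w), 25000)
      ok <- ok + (classify_waveform(f, thr) == cl)
    }
    ok / 5
  }, numeric(1))
  expect_gte(mean(acc), 0.9)
})

test_that("prevalence percentages are consistent", {
  p <- waveform_prevalence(c(rep("RS", 4), "PS"))
  expect_equal(p$percent[p$class == "RS"], 80)
  expect_equal(p$percent[p$class == "PS"], 20)
  expect_equal(sum(p$percent), 100)
  expect_equal(sum(waveform_prevalence(rep("FS", 7))$percent), 100)
  expect_warning(e <- waveform_prevalence(character(0)), "no classified")
  expect_equal(nrow(e), 0)
})
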