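test_that("iAAFT preserves the value multiset exactly and is seeded", {
  set.seed(2)
  for (rep in 1:10) {
    x <- switch(rep %% 3 + 1, rnorm(500), rexp(300), cumsum(rnorm(400)))
    s <- iaaft(x, seed = rep)
    expect_identical(sort(s$surrogate), sort(x))
    expect_false(identical(s$surrogate, x))
  }
  x <- rnorm(300)
  expect_identical(iaaft(x, seed = 9)$surrogate, iaaft(x, seed = 9)$surrogate)
  expect_false(identical(iaaft(x, seed = 9)$surrogate,
                         iaaft(x, seed = 10)$surrogate))
  expect_error(iaaft(c(x, NA)), "finite")
  expect_error(iaaft(rnorm(4)), "length")
})

test_that("iAAFT converges with a matching periodogram on a 100 s channel", {
  set.seed(3)
  x <- rnorm(1e5)          # 100 s at 1 kHz
  s <- iaaft(x, seed = 14)
  expect_true(s$converged)
  expect_lte(s$spectrum_rel_error, 1e-2)
  # structured signal too
  t <- seq(0, 100 - 1e-3, by = 1e-3)
  y <- sin(2 * pi * 1.5 * t) + 0.5 * sin(2 * pi * 3 * t) + rnorm(1e5, 0, 0.3)
  s2 <- iaaft(y, seed = 15)
  expect_true(s2$converged)
  expect_lte(s2$spectrum_rel_error, 1e-2)
})

test_that("surrogate ensembles have n x n_channels series and fixed-seed identity", {
  set.seed(4)
  rec <- raw_recording(matrix(rnorm(3 * 2000), 3), 1000)
  e <- surrogate_ensemble(rec, n = 4, seed = 8)
  expect_equal(e$n_total, 12)
  expect_length(e$surrogates, 3)
  expect_length(e$surrogates[[1]], 4)
  e2 <- surrogate_ensemble(rec, n = 4, seed = 8)
  expect_identical(e$surrogates, e2$surrogates)
  # single channel, single surrogate
  r1 <- raw_recording(matrix(rnorm(1000), 1), 1000)
  expect_equal(surrogate_ensemble(r1, n = 1, seed = 1)$n_total, 1)
})

test_that("empirical CDF is the right-continuous step function", {
  e <- ecdf_step(c(1, 2, 3))
  expect_equal(e$fun(2), 2 / 3)
  expect_equal(e$fun(0), 0)
  expect_equal(e$fun(3), 1)
  expect_equal(e$probabilities[1], 1 / 3)
  expect_error(ecdf_step(numeric(0)), "non-empty")
})

test_that("two-sample KS statistic and decision match hand-derived cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$h, 0L)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11, 12))$D, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))$D, 0.25)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("KS agrees with the reference implementation on random samples", {
  set.seed(6)
  for (rep in 1:20) {
    a <- rnorm(40 + rep); b <- rnorm(60, mean = rep / 20)
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-5)
  }
})

test_that("KS p-values are calibrated under the null", {
  set.seed(7)
  p <- replicate(1000, ks_two_sample(rnorm(60), rnorm(60))$p)
  # rejection rates near nominal at several levels (D is discrete at equal
  # n, so exact uniformity of p is not attainable; calibration of the
  # decision is what matters)
  expect_lt(abs(mean(p < 0.01) - 0.01), 0.015)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  expect_lt(abs(mean(p < 0.10) - 0.10), 0.04)
})

test_that("phase randomization cannot increase determinism of patterned inputs", {
  # asymmetric slow rhythm (harmonics phase-locked) at the analysis lag:
  # surrogates should lose ordinal determinism, i.e. gain entropy
  t <- seq(0, 30 - 1e-3, by = 1e-3)
  deltas <- vapply(1:20, function(sd0) {
    set.seed(sd0)
    x <- vapply(1:6, function(k) sin(2 * pi * 1.5 * k * t) / k, numeric(length(t)))
    x <- rowSums(x) + rnorm(length(t), 0, 0.1)
    h0 <- normalized_entropy(ordinal_pattern_distribution(x, 5, 100))
    s <- iaaft(x, seed = sd0 + 100)$surrogate
    h1 <- normalized_entropy(ordinal_pattern_distribution(s, 5, 100))
    h1 - h0
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("surrogate CE test flags patterned originals and not split halves", {
  p <- generator_params("patterned", n_channels = 6, duration_s = 40,
                        sampling_rate = 5000, seed = 31)
  r <- render_recording(p)
  cfg <- analysis_config(analysis_window = c(2, 38), n_surrogates = 8,
                         seed = 3)
  ce_rec <- ce_preprocess(slice_window(r$recording, 2, 38), cfg)
  st <- surrogate_ce_test(ce_rec, cfg)
  expect_equal(st$n_surrogate_series, 48)
  expect_equal(st$ks$h[st$ks$measure == "Cjs"], 1L)
  # surrogate pool against itself: h = 0 in >= 90% of random split halves
  v <- st$surrogate$Cjs
  set.seed(12)
  h <- replicate(50, {
    i <- sample(length(v), length(v) / 2)
    ks_two_sample(v[i], v[-i])$h
  })
  expect_gte(mean(h == 0), 0.9)
  # single-channel recording still yields one ECDF pair per measure
  one <- raw_recording(ce_rec$data[1, , drop = FALSE], ce_rec$sampling_rate)
  st1 <- surrogate_ce_test(one, analysis_config(n_surrogates = 3, seed = 4))
  expect_s3_class(st1$ecdf$Hs$original, "empirical_cdf")
  expect_s3_class(st1$ecdf$Cjs$surrogate, "empirical_cdf")
})
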