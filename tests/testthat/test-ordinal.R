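test_that("ordinal distribution matches the worked two-dimensional example", {
  d <- ordinal_pattern_distribution(c(4, 7, 9, 10, 6, 11, 3), m = 2, tau = 1)
  expect_equal(d$n_vectors, 6)
  # ascending pairs: (0,1) means the latest sample is the largest
  asc <- which(apply(d$patterns, 1, paste, collapse = "") == "01")
  expect_equal(d$probabilities[asc], 4 / 6)
  expect_equal(sum(d$probabilities), 1)
})

test_that("implementation agrees with the brute-force permutation oracle", {
  set.seed(101)
  for (rep in 1:100) {
    m <- sample(2:4, 1)
    tau <- sample(c(1, 2, 5), 1)
    n <- sample(30:80, 1)
    # mix continuous values and ties
    x <- if (rep %% 3 == 0) sample(0:4, n, replace = TRUE) else rnorm(n)
    ref <- oracle_ordinal_counts(x, m, tau)
    got <- package_ordinal_counts(x, m, tau)
    expect_equal(got[names(ref)], ref,
                 info = sprintf("rep %d m %d tau %d", rep, m, tau))
    p <- ordinal_pattern_distribution(x, m, tau)$probabilities
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("tie rule sends a constant series to the single hand-derived pattern", {
  d <- ordinal_pattern_distribution(rep(2.5, 12), m = 3, tau = 1)
  hit <- which(d$counts > 0)
  expect_length(hit, 1)
  # equal values: s_l < s_{l-1}, so the pattern is (2, 1, 0)
  expect_equal(d$patterns[hit, ], c(2L, 1L, 0L))
  expect_equal(normalized_entropy(d), 0)
})

test_that("monotone transformations leave the distribution unchanged", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(200)
    f <- sample(list(function(z) exp(z), function(z) z^3,
                     function(z) 2 * z + 7), 1)[[1]]
    a <- ordinal_pattern_distribution(x, 3, 2)
    b <- ordinal_pattern_distribution(f(x), 3, 2)
    expect_identical(a$counts, b$counts)
  }
})

test_that("entropy and complexity hit their analytic limits", {
  # degenerate -> Hs = 0, Cjs = 0
  expect_equal(normalized_entropy(c(1, 0)), 0)
  expect_equal(statistical_complexity(c(1, 0, 0, 0, 0, 0)), 0)
  # uniform -> Hs = 1, Cjs = 0
  expect_equal(normalized_entropy(rep(1 / 24, 24)), 1)
  expect_equal(statistical_complexity(rep(1 / 24, 24)), 0)
  # closed form for M = 2, P = (2/3, 1/3)
  expect_equal(normalized_entropy(c(2 / 3, 1 / 3)), 0.91830, tolerance = 1e-5)
  # strictly increasing sequence: single pattern
  inc <- ordinal_pattern_distribution(seq_len(40), m = 4, tau = 1)
  expect_equal(max(inc$probabilities), 1)
  expect_equal(normalized_entropy(inc), 0)
})

test_that("complexity matches a direct evaluation of its formulas", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(c(2, 6, 24, 120), 1)
    p <- rgamma(n, 1); p <- p / sum(p)
    ref <- oracle_ce(p)
    expect_equal(normalized_entropy(p), ref$hs, tolerance = 1e-12)
    expect_equal(statistical_complexity(p), ref$cjs, tolerance = 1e-12)
    expect_gte(ref$cjs, 0)
    expect_lte(ref$hs, 1)
  }
  # the M = 2 example evaluated both ways
  expect_equal(statistical_complexity(c(2 / 3, 1 / 3)),
               oracle_ce(c(2 / 3, 1 / 3))$cjs, tolerance = 1e-12)
})

test_that("ce_plane separates noise from patterned channels", {
  cfg <- analysis_config()
  # seeded white noise at 1 kHz, 100 s: near-maximal entropy
  set.seed(11)
  noise <- raw_recording(matrix(rnorm(1e5), 1), 1000)
  pt <- ce_plane(noise, cfg)
  expect_equal(pt$n_vectors, 1e5 - 400)
  expect_gt(pt$Hs, 0.97)
  expect_lt(pt$Cjs, 0.05)

  # 1 Hz sawtooth: few patterns occur
  t <- seq(0, 100 - 1e-3, by = 1e-3)
  saw <- raw_recording(matrix((t %% 1), 1), 1000)
  ps <- ce_plane(saw, cfg)
  expect_lt(ps$Hs, 0.5)

  # identical channels give identical points
  two <- raw_recording(rbind(noise$data[1, ], noise$data[1, ]), 1000)
  pts <- ce_plane(two, cfg)
  expect_equal(pts$Hs[1], pts$Hs[2])
  expect_equal(pts$Cjs[1], pts$Cjs[2])

  # channel shorter than the embedding span
  short <- raw_recording(matrix(rnorm(300), 1), 1000)
  expect_error(ce_plane(short, cfg), "embedding span")
})
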