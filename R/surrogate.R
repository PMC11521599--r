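#' iAAFT surrogate of a time series
#'
#' Iterative amplitude-adjusted Fourier transform surrogate: starting from a
#' seeded random permutation of `x`, alternately (i) imposes the original
#' amplitude spectrum in the Fourier domain and (ii) rank-remaps the result
#' onto the sorted original values, until the rank order is unchanged on two
#' consecutive iterations (an exact fixed point), the relative
#' amplitude-spectrum discrepancy falls below `spec_tol` (the surrogate is
#' spectrally faithful), the discrepancy stalls (relative improvement per
#' iteration below `stall_tol`, checked after 10 iterations), or `max_iter`
#' is reached. The surrogate has
#' exactly the same value multiset as `x` and (at convergence) nearly the
#' same power spectrum, but randomized Fourier phases — the null model of a
#' stationary linear stochastic process observed through a static monotone
#' function.
#'
#' @param x numeric vector, length >= 8, finite.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial permutation.
#' @param stall_tol relative spectral-discrepancy improvement below which
#'   the iteration is considered converged.
#' @param spec_tol absolute relative amplitude-spectrum discrepancy below
#'   which the iteration stops (corresponds to roughly twice that value in
#'   periodogram relative error).
#' @return list with `surrogate`, `iterations`, `converged`, and
#'   `spectrum_rel_error` (relative L2 error of the surrogate periodogram
#'   against the original).
#' @export
iaaft <- function(x, max_iter = 1000, seed = 1L, stall_tol = 0.05,
                  spec_tol = 3.5e-3) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("`x` must be finite numeric")
  if (length(x) < 8) stop("`x` must have length >= 8")
  set.seed(seed)
  y0 <- sample(x)
  .iaaft_core(as.numeric(x), as.numeric(y0), as.integer(max_iter),
              stall_tol, spec_tol)
}

#' iAAFT surrogate ensembles for every channel of a recording
#'
#' Generates `n` surrogates per channel with decoupled seed substreams.
#' With `keep_surrogates = FALSE` only iteration counts and convergence
#' flags are retained and per-surrogate results are handed to `fun`
#' (and then discarded), which keeps 49 surrogates x 60 channels of
#' 1e5-sample series within memory reach.
#'
#' @param rec a [raw_recording()] (already prepared by [ce_preprocess()]
#'   when used for complexity-entropy testing).
#' @param n surrogates per channel (default 49).
#' @param seed global seed.
#' @param max_iter iteration cap per surrogate.
#' @param keep_surrogates retain the surrogate series? Default `TRUE`.
#' @param fun optional `function(surrogate, channel, index)` applied to each
#'   surrogate series as it is produced; its results are collected in
#'   `$values`.
#' @return object of class `surrogate_ensemble_set`: list with `channel_ids`,
#'   `n_surrogates`, `iterations` (channels x n matrix), `converged`
#'   (matrix), `surrogates` (list of lists or `NULL`), `values` (list or
#'   `NULL`), `n_total`.
#' @export
surrogate_ensemble <- function(rec, n = 49, seed = 1L, max_iter = 1000,
                               keep_surrogates = TRUE, fun = NULL) {
  stopifnot(inherits(rec, "raw_recording"), n >= 1)
  nch <- nrow(rec$data)
  iterations <- matrix(NA_integer_, nch, n)
  converged <- matrix(NA, nch, n)
  surrogates <- if (keep_surrogates) vector("list", nch) else NULL
  values <- if (!is.null(fun)) vector("list", nch) else NULL
  for (ch in seq_len(nch)) {
    if (keep_surrogates) surrogates[[ch]] <- vector("list", n)
    if (!is.null(fun)) values[[ch]] <- vector("list", n)
    for (j in seq_len(n)) {
      s <- iaaft(rec$data[ch, ], max_iter = max_iter,
                 seed = stage_seed(seed, "iaaft", (ch - 1L) * n + j))
      iterations[ch, j] <- s$iterations
      converged[ch, j] <- s$converged
      if (keep_surrogates) surrogates[[ch]][[j]] <- s$surrogate
      if (!is.null(fun)) values[[ch]][[j]] <- fun(s$surrogate, ch, j)
    }
  }
  structure(list(channel_ids = rec$channel_ids, n_surrogates = n,
                 iterations = iterations, converged = converged,
                 surrogates = surrogates, values = values,
                 n_total = nch * n),
            class = "surrogate_ensemble_set")
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step function `F(t) = #{x_i <= t} / n`, with
#' `F(min) = 1/n` and `F(max) = 1`.
#'
#' @param values non-empty numeric vector.
#' @return object of class `empirical_cdf`: list with sorted `values`,
#'   step `probabilities`, and `fun` (a vectorized evaluator).
#' @export
ecdf_step <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)))
    stop("`values` must be non-empty and finite")
  s <- sort(values)
  n <- length(s)
  f <- function(t) vapply(t, function(ti) sum(s <= ti), numeric(1)) / n
  structure(list(values = s, probabilities = seq_len(n) / n, fun = f),
            class = "empirical_cdf")
}

# asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^{k-1} e^{-2k^2 lambda^2}
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|` over the pooled sample, with the p-value from the
#' asymptotic Kolmogorov distribution at effective size
#' `n_eff = n_a n_b / (n_a + n_b)`; the null (same distribution) is
#' rejected (`h = 1`) when `p < alpha`.
#'
#' @param a,b non-empty numeric samples.
#' @param alpha significance level (default 0.05).
#' @return list with `D`, `p`, `h`.
#' @export
ks_two_sample <- function(a, b, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  fa <- ecdf_step(a)$fun(pooled)
  fb <- ecdf_step(b)$fun(pooled)
  D <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  list(D = D, p = p, h = as.integer(p < alpha))
}

#' Surrogate test of the complexity-entropy measures
#'
#' Computes `Hs` and `Cjs` for every original channel and for `n` iAAFT
#' surrogates per channel (same embedding settings), pools the surrogate
#' measures, and compares original vs surrogate empirical CDFs with the
#' two-sample Kolmogorov-Smirnov test, separately for entropy and
#' complexity. Surrogate series are streamed (not retained).
#'
#' @param rec a [raw_recording()] already prepared by [ce_preprocess()].
#' @param config an [analysis_config()] (`ce_m`, `ce_tau`, `n_surrogates`,
#'   `surrogate_max_iter`, `alpha`, `seed`).
#' @return list with `original` (the [ce_plane()] data frame), `surrogate`
#'   (data frame `channel`, `surrogate`, `Hs`, `Cjs`), `ks` (data frame
#'   `measure`, `D`, `p`, `h`), `ecdf` (list of `empirical_cdf` pairs),
#'   and `n_surrogate_series`.
#' @export
surrogate_ce_test <- function(rec, config = analysis_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  original <- ce_plane(rec, config)
  m <- config$ce_m; tau <- config$ce_tau
  ce_of <- function(x, ch, j) {
    d <- ordinal_pattern_distribution(x, m = m, tau = tau)
    c(Hs = normalized_entropy(d), Cjs = statistical_complexity(d))
  }
  ens <- surrogate_ensemble(rec, n = config$n_surrogates, seed = config$seed,
                            max_iter = config$surrogate_max_iter,
                            keep_surrogates = FALSE, fun = ce_of)
  surr <- do.call(rbind, lapply(seq_along(ens$values), function(ch) {
    v <- do.call(rbind, ens$values[[ch]])
    data.frame(channel = rec$channel_ids[ch], surrogate = seq_len(nrow(v)),
               Hs = v[, "Hs"], Cjs = v[, "Cjs"], stringsAsFactors = FALSE)
  }))
  rownames(surr) <- NULL
  ks <- do.call(rbind, lapply(c("Hs", "Cjs"), function(meas) {
    r <- ks_two_sample(original[[meas]], surr[[meas]], alpha = config$alpha)
    data.frame(measure = meas, D = r$D, p = r$p, h = r$h,
               stringsAsFactors = FALSE)
  }))
  list(original = original, surrogate = surr, ks = ks,
       ecdf = list(Hs = list(original = ecdf_step(original$Hs),
                             surrogate = ecdf_step(surr$Hs)),
                   Cjs = list(original = ecdf_step(original$Cjs),
                              surrogate = ecdf_step(surr$Cjs))),
       n_surrogate_series = ens$n_total,
       iterations = ens$iterations, converged = ens$converged)
}
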