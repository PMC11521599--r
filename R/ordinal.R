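#' @useDynLib astromea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# all permutations of 0..(m-1), lexicographic order, as an m! x m matrix
all_permutations <- function(m) {
  if (m == 1) return(matrix(0L, 1, 1))
  sub <- all_permutations(m - 1)
  out <- matrix(0L, factorial(m), m)
  row <- 1L
  for (first in 0L:(m - 1L)) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    n <- nrow(rest)
    out[row:(row + n - 1L), 1] <- first
    out[row:(row + n - 1L), -1] <- rest
    row <- row + n
  }
  out
}

# base-m code of the rank-position vector of each pattern (s0..s_{m-1});
# matches the coding used by the C++ window scanner
pattern_codes <- function(perms) {
  m <- ncol(perms)
  pos <- matrix(0L, nrow(perms), m)
  for (l in seq_len(m)) pos[cbind(seq_len(nrow(perms)), perms[, l] + 1L)] <- l - 1L
  as.integer(pos %*% m^(0:(m - 1)))
}

#' Ordinal-pattern distribution of a time series
#'
#' Maps every lagged embedding window of `x` to its ordinal pattern: the
#' permutation `(s0, ..., s_{M-1})` of lag indices ordering the window's
#' components descendingly, `x[u - s_{M-1} tau] <= ... <= x[u - s0 tau]`,
#' with ties resolved towards the smaller lag taking the later slot
#' (`s_l < s_{l-1}` when the tied values are equal). Relative frequencies
#' over the `M!` possible patterns form the distribution used by
#' [normalized_entropy()] and [statistical_complexity()].
#'
#' @param x numeric vector, length at least `(m - 1) * tau + 1`.
#' @param m embedding dimension M (>= 2). `m! ` patterns exist; keep `m`
#'   small enough that the series can populate them (`length(x) >> m!`).
#' @param tau embedding lag in samples (>= 1).
#'
#' @return an object of class `ordinal_distribution`: list with `m`, `tau`,
#'   `patterns` (an `m! x m` matrix of permutations, lexicographic order),
#'   `counts`, `probabilities`, `n_vectors`.
#' @export
ordinal_pattern_distribution <- function(x, m, tau = 1) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("`x` must be finite numeric")
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2) stop("embedding dimension m must be >= 2")
  if (tau < 1) stop("lag tau must be >= 1")
  if (length(x) < (m - 1) * tau + 1)
    stop("series too short: need at least (m-1)*tau + 1 samples")
  codes <- .ordinal_codes(as.numeric(x), m, tau)
  perms <- all_permutations(m)
  idx <- match(codes, pattern_codes(perms))
  counts <- tabulate(idx, nbins = nrow(perms))
  structure(
    list(m = m, tau = tau, patterns = perms, counts = counts,
         probabilities = counts / sum(counts), n_vectors = length(codes)),
    class = "ordinal_distribution"
  )
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> M = %d, tau = %d, %d windows, %d/%d patterns observed\n",
              x$m, x$tau, x$n_vectors, sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

# Shannon entropy, natural log, 0*log(0) := 0
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution divided by its
#' maximum `log(M!)`, so `Hs` lies in `[0, 1]`: 0 for a degenerate
#' (single-pattern) distribution, 1 for the uniform one. Base-free by
#' normalization.
#'
#' @param p an [ordinal_pattern_distribution()] or a bare probability vector.
#' @return `Hs` in `[0, 1]`.
#' @export
normalized_entropy <- function(p) {
  probs <- if (inherits(p, "ordinal_distribution")) p$probabilities else p
  stopifnot(abs(sum(probs) - 1) < 1e-9, all(probs >= 0))
  shannon(probs) / log(length(probs))
}

#' Statistical complexity (Jensen-Shannon disequilibrium x entropy)
#'
#' `Cjs = Q0 * Je * Hs`, where `Je = S[(P + Pe)/2] - S[P]/2 - S[Pe]/2` is
#' the Jensen-Shannon divergence between the pattern distribution `P` and
#' the uniform distribution `Pe` over the `M!` patterns, and `Q0` is the
#' normalization constant making the disequilibrium reach 1 at its maximum
#' (a degenerate `P`):
#' `Q0 = -2 / ( ((N+1)/N) log(N+1) - 2 log(2N) + log(N) )` with `N = M!`.
#' `Cjs` vanishes both for fully random (uniform `P`) and fully ordered
#' (degenerate `P`) series and is maximal in between.
#'
#' @inheritParams normalized_entropy
#' @return `Cjs >= 0`.
#' @export
statistical_complexity <- function(p) {
  probs <- if (inherits(p, "ordinal_distribution")) p$probabilities else p
  stopifnot(abs(sum(probs) - 1) < 1e-9, all(probs >= 0))
  n <- length(probs)
  pe <- rep(1 / n, n)
  je <- shannon((probs + pe) / 2) - shannon(probs) / 2 - shannon(pe) / 2
  q0 <- -2 / (((n + 1) / n) * log(n + 1) - 2 * log(2 * n) + log(n))
  hs <- shannon(probs) / log(n)
  q0 * je * hs
}

#' Complexity-entropy plane of a recording
#'
#' Computes one `(Hs, Cjs)` point per channel from the ordinal-pattern
#' distribution with embedding dimension `config$ce_m` and lag
#' `config$ce_tau`. The recording is expected to be already prepared by
#' [ce_preprocess()] (lowpassed and resampled); pass `preprocess = TRUE` to
#' run that chain first.
#'
#' @param rec a [raw_recording()].
#' @param config an [analysis_config()].
#' @param preprocess run [ce_preprocess()] on `rec` first? Default `FALSE`.
#' @return data frame with columns `channel`, `Hs`, `Cjs`, `n_vectors`,
#'   `m`, `tau`.
#' @export
ce_plane <- function(rec, config = analysis_config(), preprocess = FALSE) {
  stopifnot(inherits(rec, "raw_recording"))
  if (preprocess) rec <- ce_preprocess(rec, config)
  m <- config$ce_m; tau <- config$ce_tau
  if (ncol(rec$data) < (m - 1) * tau + 1)
    stop("channels shorter than the embedding span (m-1)*tau + 1")
  res <- lapply(seq_len(nrow(rec$data)), function(ch) {
    dist <- ordinal_pattern_distribution(rec$data[ch, ], m = m, tau = tau)
    data.frame(channel = rec$channel_ids[ch],
               Hs = normalized_entropy(dist),
               Cjs = statistical_complexity(dist),
               n_vectors = dist$n_vectors, m = m, tau = tau,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
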