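# Independent brute-force oracle for ordinal patterns: for each embedding
# window, try every permutation s = (s0, ..., s_{m-1}) of the lag indices
# and keep the unique one whose descending order (ties resolved towards the
# smaller lag in the later slot) matches the window. Returns counts named
# by the permutation string "s0 s1 ... s_{m-1}".
oracle_perms <- function(m) {
  if (m == 1) return(list(0L))
  out <- list()
  for (first in 0:(m - 1)) {
    for (rest in oracle_perms(m - 1)) {
      rest2 <- ifelse(rest >= first, rest + 1L, rest)
      out[[length(out) + 1L]] <- c(first, rest2)
    }
  }
  out
}

oracle_ordinal_counts <- function(x, m, tau) {
  perms <- oracle_perms(m)
  labels <- vapply(perms, paste, character(1), collapse = " ")
  counts <- stats::setNames(integer(length(perms)), labels)
  span <- (m - 1) * tau
  for (u in (span + 1):length(x)) {
    v <- function(j) x[u - j * tau]   # lag j component
    hit <- NA_integer_
    for (pi in seq_along(perms)) {
      s <- perms[[pi]]
      ok <- TRUE
      for (l in 2:m) {
        a <- v(s[l - 1]); b <- v(s[l])   # must be non-increasing
        if (a < b || (a == b && s[l] >= s[l - 1])) { ok <- FALSE; break }
      }
      if (ok) { hit <- pi; break }
    }
    stopifnot(!is.na(hit))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# counts from the package, named the same way
package_ordinal_counts <- function(x, m, tau) {
  d <- ordinal_pattern_distribution(x, m, tau)
  stats::setNames(d$counts, apply(d$patterns, 1, paste, collapse = " "))
}

# direct evaluation of the complexity-entropy formulas on a probability
# vector (independent of the package's implementation)
oracle_ce <- function(p) {
  n <- length(p)
  S <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hs <- S(p) / log(n)
  pe <- rep(1 / n, n)
  je <- S((p + pe) / 2) - S(p) / 2 - S(pe) / 2
  q0 <- -2 / (((n + 1) / n) * log(n + 1) - 2 * log(2 * n) + log(n))
  list(hs = hs, cjs = q0 * je * hs)
}

# deterministic 20-burst spike train: bursts of 5 spikes at 10 ms ISI,
# onsets 2 s apart
twenty_burst_train <- function(window_s = 100) {
  ts <- as.vector(vapply(seq(0.5, by = 2, length.out = 20),
                         function(o) o + (0:4) * 0.010, numeric(5)))
  spike_train(list(ch01 = data.frame(time = sort(ts), polarity = -1L,
                                     amplitude = -50)),
              window_s = window_s)
}

# noisy cutout matrix from a template
noisy_cutouts <- function(template, n, noise_sd, seed) {
  set.seed(seed)
  t(replicate(n, template + stats::rnorm(length(template), 0, noise_sd)))
}

as_cutouts <- function(waveforms, sampling_rate = 25000) {
  structure(list(waveforms = waveforms,
                 channel = rep("ch01", nrow(waveforms)),
                 time = seq_len(nrow(waveforms)) / 1000,
                 sampling_rate = sampling_rate, pre_ms = 1, post_ms = 2,
                 n_boundary_skipped = 0L),
            class = "spike_cutouts")
}

wf_classes <- c("RS", "FS", "TS", "CS", "PS")
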