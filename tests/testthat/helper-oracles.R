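# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately avoid the code paths they check.

# Exhaustive 2^n enumeration of P(sum Bernoulli(ps) >= k).
pb_tail_oracle <- function(ps, k) {
  n <- length(ps)
  if (k == 0) return(1)
  if (k > n) return(0)
  combos <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(combos, 1L, function(b) prod(ifelse(b == 1, ps, 1 - ps)))
  sum(probs[rowSums(combos) >= k])
}

# Exhaustive sign-flip enumeration of the paired frequency-change test.
signflip_oracle <- function(d) {
  n <- length(d)
  obs <- sum(d)
  combos <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  nets <- combos %*% d
  mean(abs(nets) >= abs(obs))
}

# Exhaustive window enumeration for the longest two-state alternation.
oscillation_oracle <- function(cn) {
  n <- length(cn)
  best <- min(n, 1L)
  if (n < 2L) return(best)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- cn[i:j]
    ok <- length(unique(w)) <= 2L && all(diff(w) != 0)
    if (ok && length(w) >= 3L)
      ok <- all(w[-(1:2)] == w[seq_len(length(w) - 2L)])
    if (ok) best <- max(best, length(w))
  }
  best
}

# Any window of >= m consecutive positions with mean spacing <= d?
kataegis_window_oracle <- function(pos, m = 6L, d = 1000) {
  pos <- sort(pos)
  n <- length(pos)
  if (n < m) return(FALSE)
  for (i in seq_len(n - m + 1L)) for (j in (i + m - 1L):n)
    if ((pos[j] - pos[i]) / (j - i) <= d) return(TRUE)
  FALSE
}

# SV crossing via the one-endpoint-inside formulation.
interleaved_oracle <- function(starts, ends) {
  n <- length(starts)
  a1 <- pmin(starts, ends); a2 <- pmax(starts, ends)
  crossed <- rep(FALSE, n)
  if (n >= 2L) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    inside1 <- a1[j] > a1[i] && a1[j] < a2[i]
    inside2 <- a2[j] > a1[i] && a2[j] < a2[i]
    if (xor(inside1, inside2)) crossed[i] <- TRUE
  }
  sum(crossed)
}

# Small helper: minimal bundle-like list for chronology tests.
make_mini_bundle <- function(mutations, segments, metadata,
                             genome = synthetic_genome()) {
  list(mutations = mutations, segments = segments, metadata = metadata,
       genome = genome)
}
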