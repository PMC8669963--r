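# Independent oracles, deliberately coded with naive scalar arithmetic and
# kept free of any package internals they are used to check.

# One explicit-Euler step, scalar loops, literal sum over j != i of
# K[i,j] * sin(ph[j] - ph[i]) (attractive convention).
oracle_euler_step <- function(phases, omega, K, drive, dt = 1) {
  n <- length(phases)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + K[i, j] * sin(phases[j] - phases[i])
    }
    out[i] <- phases[i] + dt * (omega[i] + acc / n + drive[i])
  }
  out
}

# Pairwise PLV via explicit cosine/sine accumulators.
oracle_plv <- function(x, y) {
  d <- x - y
  re <- sum(cos(d)) / length(d)
  im <- sum(-sin(d)) / length(d)
  sqrt(re^2 + im^2)
}

# Grand-average PLV by brute-force enumeration of unordered pairs.
oracle_grand_plv <- function(phases) {
  n <- ncol(phases)
  vals <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, oracle_plv(phases[, i], phases[, j]))
    }
  }
  mean(vals)
}

# Brute-force pulse-onset count on the iteration grid.
oracle_onset_count <- function(freq_hz, iter_ms, n_iterations, start = 0) {
  cnt <- 0L
  for (t in seq.int(start, start + n_iterations - 1)) {
    prev <- if (t == 0) -1 else floor((t - 1) * iter_ms / 1000 * freq_hz)
    if (t == 0 || floor(t * iter_ms / 1000 * freq_hz) > prev) cnt <- cnt + 1L
  }
  cnt
}
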