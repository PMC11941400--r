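# Brute-force oracles kept deliberately naive and independent of the
# package's vectorized implementations.

# maximal runs strictly inside (lo, hi), by explicit loop
brute_laminar_lengths <- function(series, lo, hi) {
  out <- integer(0)
  run <- 0L
  for (v in series) {
    if (v > lo && v < hi) {
      run <- run + 1L
    } else if (run > 0L) {
      out <- c(out, run)
      run <- 0L
    }
  }
  if (run > 0L) out <- c(out, run)
  out
}

# upward threshold crossings by explicit pairwise scan
brute_onsets <- function(series, threshold) {
  out <- integer(0)
  for (i in seq_along(series)) {
    if (series[i] >= threshold && (i == 1L || series[i - 1L] < threshold))
      out <- c(out, i)
  }
  out
}

# a modest coupled run shared by several tests
small_spike_train <- function(n = 2e5, seed = 11) {
  generate_spike_train(cfg = coupling_config(n_samples = n, seed = seed))
}
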