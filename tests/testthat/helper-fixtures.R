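# Shared fixtures: all synthetic, built in code at test time.

# A short clean segment (no artifacts) for unit tests that do not need the
# full 120 s analysis window.
quick_segment <- function(label = "medium", duration_s = 8, seed = 1,
                          montage = standard_montage()) {
  simulate_segment(label, montage = montage,
                   artifacts = default_artifact_config(blink_rate = 0),
                   fs = 256, duration_s = duration_s, seed = seed)
}

# A clean multichannel recording: iid Gaussian channels.
quick_recording <- function(n_s = 4, fs = 256, sd = 10, seed = 1) {
  set.seed(seed)
  m <- standard_montage()
  raw_recording(matrix(stats::rnorm(20 * n_s * fs, sd = sd), nrow = 20),
                fs = fs, montage = m)
}

# Planted-signal design: p mostly-noise features, the first `n_signal` carry
# an ordered class effect (low < medium < high in the feature mean).
planted_matrix <- function(n_per_class = 20, p = 228, n_signal = 3,
                           sep = 1.5, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  y <- factor(rep(workload_levels(), each = n_per_class),
              levels = workload_levels())
  X <- matrix(stats::rnorm(3 * n_per_class * p), ncol = p)
  mu <- c(low = -sep, medium = 0, high = sep)
  for (j in seq_len(n_signal)) {
    X[, j] <- X[, j] * noise_sd + mu[as.character(y)]
  }
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(X = X, y = y)
}

# Well-separated 3-class Gaussian blobs for classifier tests.
blob_data <- function(n_per_class = 12, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  y <- factor(rep(workload_levels(), each = n_per_class),
              levels = workload_levels())
  centers <- rbind(low = c(rep(0, d)), medium = c(sep, rep(0, d - 1)),
                   high = c(0, sep, rep(0, d - 2)))
  X <- centers[as.character(y), ] + matrix(stats::rnorm(length(y) * d), ncol = d)
  dimnames(X) <- list(NULL, paste0("x", seq_len(d)))
  list(X = X, y = y)
}
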