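# Independent oracles used across tests.

# Smoothed HMM marginals by exhaustive enumeration over all 5^T state paths.
# O(5^T) by construction; usable only for tiny T, which is the point: it
# shares no code with the forward-backward implementation.
brute_force_marginals <- function(log_likelihoods, transition, initial) {
  T_ <- nrow(log_likelihoods)
  paths <- as.matrix(expand.grid(rep(list(1:5), T_)))
  logw <- apply(paths, 1, function(s) {
    lw <- log(initial[s[1]]) + log_likelihoods[1, s[1]]
    if (T_ > 1) {
      for (t in 2:T_) {
        lw <- lw + log(transition[s[t - 1], s[t]]) + log_likelihoods[t, s[t]]
      }
    }
    lw
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  out <- matrix(0, T_, 5)
  for (t in 1:T_) {
    for (i in 1:5) out[t, i] <- sum(w[paths[, t] == i])
  }
  out
}

random_stochastic_matrix <- function() {
  m <- matrix(stats::rexp(25) + 0.01, 5, 5)
  m / rowSums(m)
}

random_simplex <- function(concentration = 1) {
  x <- stats::rgamma(5, concentration)
  if (sum(x) == 0) x <- rep(1, 5)
  x / sum(x)
}

# A small, fast synthetic night: lower sample rate, clean or noisy spectra.
quick_night <- function(n_epochs = 80, seed = 1, fs = 125, jitter = 0.6,
                        fragmentation = 0) {
  cfg <- synthetic_config(n_epochs = n_epochs, sample_rate_hz = fs,
                          band_jitter_sdlog = jitter,
                          fragmentation = fragmentation, seed = seed)
  simulate_night(cfg)
}

quick_features <- function(night) {
  fs <- night$config$sample_rate_hz
  extract_features(night$signal, fs)
}
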