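# Synthetic polysomnography: seeded Markov stage dynamics plus single-channel
# EEG with stage-specific band spectra. Stands in for real recordings so the
# full staging/uncertainty/review pipeline is testable end to end.

#' Derive a stream-specific seed from a global seed
#'
#' All randomness in the package flows from one integer seed; independent
#' streams (hypnogram draw, EEG noise, reviewer coin flips, MLP init) use
#' seeds derived deterministically from it so that components can be re-run
#' in isolation without perturbing one another.
#'
#' @param seed Integer global seed.
#' @param stream Character tag or integer naming the stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  m <- 2147483647                       # 2^31 - 1, Lehmer modulus
  h <- if (is.character(stream)) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  } else {
    as.numeric(stream) * 2654435761
  }
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + (h %% m)) %% m
  as.integer(x)
}

with_stream_seed <- function(seed, stream, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(derive_seed(seed, stream))
  }
  expr
}

#' Default stage-transition dynamics of the simulator
#'
#' `default_transition_matrix()` is a strongly diagonal 5x5 row-stochastic
#' matrix (self-transition 0.80-0.92) with off-diagonal mass placed on
#' physiologically ordered moves (W<->N1, N1->N2, N2<->N3, N2->REM).
#' `fragmented_transition_matrix()` is the near-uniform matrix toward which
#' the chain is mixed as the fragmentation parameter grows; heavy mixing
#' yields the rapid stage switching typical of severe sleep apnea.
#' `default_initial_distribution()` starts nights predominantly awake.
#'
#' These are stylized package constants: they are not fitted to any cohort,
#' and their only job is to produce plausible whole-night architecture.
#'
#' @return A 5x5 matrix with rows/columns ordered per [stage_labels()], or a
#'   length-5 probability vector.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    # to:   W      REM    N1     N2     N3
    0.920, 0.005, 0.060, 0.010, 0.005,  # from W
    0.020, 0.900, 0.030, 0.040, 0.010,  # from REM
    0.050, 0.030, 0.800, 0.110, 0.010,  # from N1
    0.010, 0.020, 0.030, 0.900, 0.040,  # from N2
    0.005, 0.005, 0.010, 0.080, 0.900   # from N3
  ), nrow = 5, byrow = TRUE, dimnames = list(stage_labels(), stage_labels()))
  m
}

#' @rdname default_transition_matrix
#' @export
fragmented_transition_matrix <- function() {
  matrix(0.2, 5, 5, dimnames = list(stage_labels(), stage_labels()))
}

#' @rdname default_transition_matrix
#' @export
default_initial_distribution <- function() {
  stats::setNames(c(0.90, 0.01, 0.05, 0.03, 0.01), stage_labels())
}

#' Default per-stage EEG band-power profiles
#'
#' Relative power in the five classical EEG bands (delta 0.5-4, theta 4-8,
#' alpha 8-12, sigma 12-16, beta 16-30 Hz), one row per stage. Each row sums
#' to 1. The profiles follow textbook sleep EEG: alpha/beta-rich wake,
#' theta-dominant REM, mixed low-amplitude N1, sigma (spindle-band) activity
#' in N2, and delta-dominant N3. N1 deliberately overlaps its neighbours -
#' it is the stage human scorers disagree on most - so the simulator yields
#' a realistic mix of certain and uncertain epochs.
#'
#' @return A 5x5 matrix, rows = stages, columns = bands.
#' @export
default_stage_spectra <- function() {
  m <- matrix(c(
    # delta theta alpha sigma  beta
    0.05, 0.10, 0.45, 0.10, 0.30,  # W
    0.10, 0.45, 0.15, 0.10, 0.20,  # REM
    0.15, 0.35, 0.25, 0.15, 0.10,  # N1
    0.30, 0.15, 0.10, 0.35, 0.10,  # N2
    0.70, 0.15, 0.05, 0.05, 0.05   # N3
  ), nrow = 5, byrow = TRUE,
  dimnames = list(stage_labels(), c("delta", "theta", "alpha", "sigma", "beta")))
  m
}

spectral_band_edges <- function() {
  matrix(c(0.5, 4, 4, 8, 8, 12, 12, 16, 16, 30), nrow = 5, byrow = TRUE,
         dimnames = list(c("delta", "theta", "alpha", "sigma", "beta"),
                         c("low", "high")))
}

#' Configuration of a synthetic study night
#'
#' @param transition_matrix 5x5 row-stochastic base transition matrix.
#' @param initial_distribution Length-5 probability vector over stages.
#' @param stage_spectra 5x5 matrix of non-negative relative band powers
#'   (rows = stages per [stage_labels()], columns = delta/theta/alpha/sigma/
#'   beta bands).
#' @param noise_floor Variance of the broadband white-noise component added
#'   to every epoch, relative to unit total band power (default 0.4).
#' @param band_jitter_sdlog Standard deviation (log scale) of the lognormal
#'   per-epoch, per-band power fluctuation (default 0.6). Real sleep EEG
#'   band powers vary severalfold between epochs of the same stage; without
#'   this within-stage variability every epoch would be classified with
#'   near-certainty and the uncertainty machinery would have nothing to do.
#'   0 disables the jitter.
#' @param fragmentation Non-negative mixing weight `w` toward the
#'   near-uniform [fragmented_transition_matrix()]; the effective chain is
#'   `(1 - w) * base + w * fragmented` with `w = min(fragmentation, 1)`.
#'   Serves as a severity proxy for sleep-fragmenting disease (0 = healthy).
#' @param sample_rate_hz EEG sample rate (default 250).
#' @param n_epochs Number of 30-s epochs per night (default 960, i.e. 8 h).
#' @param epoch_seconds Epoch duration (default 30).
#' @param seed Integer seed; all draws for this night derive from it.
#' @return An object of class `"synthetic_config"`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_epochs = 40, seed = 7)
#' night <- simulate_night(cfg)
#' print(night$hypnogram)
synthetic_config <- function(transition_matrix = default_transition_matrix(),
                             initial_distribution = default_initial_distribution(),
                             stage_spectra = default_stage_spectra(),
                             noise_floor = 0.4,
                             band_jitter_sdlog = 0.6,
                             fragmentation = 0,
                             sample_rate_hz = 250,
                             n_epochs = 960,
                             epoch_seconds = 30,
                             seed = 1L) {
  cfg <- structure(list(
    transition_matrix = as.matrix(transition_matrix),
    initial_distribution = as.numeric(initial_distribution),
    stage_spectra = as.matrix(stage_spectra),
    noise_floor = noise_floor,
    band_jitter_sdlog = band_jitter_sdlog,
    fragmentation = fragmentation,
    sample_rate_hz = sample_rate_hz,
    n_epochs = as.integer(n_epochs),
    epoch_seconds = epoch_seconds,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_stochastic_matrix <- function(m, what = "transition_matrix", tol = 1e-12) {
  if (!is.matrix(m) || any(dim(m) != c(5, 5))) {
    stop(what, " must be a 5x5 matrix", call. = FALSE)
  }
  if (any(m < 0)) stop(what, " has negative entries", call. = FALSE)
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    stop(what, " row(s) ", paste(bad, collapse = ", "),
         " (", paste(stage_labels()[bad], collapse = ", "),
         ") do not sum to 1 (sums: ", paste(signif(rs[bad], 10), collapse = ", "),
         ")", call. = FALSE)
  }
  invisible(m)
}

validate_synthetic_config <- function(cfg) {
  validate_stochastic_matrix(cfg$transition_matrix)
  p0 <- cfg$initial_distribution
  if (length(p0) != 5 || any(p0 < 0) || abs(sum(p0) - 1) > 1e-12) {
    stop("initial_distribution must be a length-5 probability vector summing to 1",
         call. = FALSE)
  }
  if (any(dim(cfg$stage_spectra) != c(5, 5)) || any(cfg$stage_spectra < 0)) {
    stop("stage_spectra must be a 5x5 matrix of non-negative band powers",
         call. = FALSE)
  }
  if (cfg$noise_floor < 0) stop("noise_floor must be >= 0", call. = FALSE)
  if (cfg$band_jitter_sdlog < 0) stop("band_jitter_sdlog must be >= 0", call. = FALSE)
  if (cfg$fragmentation < 0) stop("fragmentation must be >= 0", call. = FALSE)
  if (cfg$sample_rate_hz <= 0) stop("sample_rate_hz must be positive", call. = FALSE)
  if (cfg$n_epochs < 0) stop("n_epochs must be non-negative", call. = FALSE)
  if (cfg$epoch_seconds <= 0) stop("epoch_seconds must be positive", call. = FALSE)
  invisible(cfg)
}

effective_transition_matrix <- function(cfg) {
  w <- min(cfg$fragmentation, 1)
  (1 - w) * cfg$transition_matrix + w * fragmented_transition_matrix()
}

#' Simulate a ground-truth hypnogram
#'
#' Draws a stage sequence from the first-order Markov chain defined by the
#' configuration, after mixing the base transition matrix toward the
#' fragmented matrix according to `fragmentation`.
#'
#' @param config A [synthetic_config()].
#' @return A [hypnogram()] of `config$n_epochs` epochs.
#' @export
generate_hypnogram <- function(config) {
  validate_synthetic_config(config)
  tm <- effective_transition_matrix(config)
  n <- config$n_epochs
  if (n == 0L) return(hypnogram(integer(0), epoch_seconds = config$epoch_seconds))
  with_stream_seed(config$seed, "hypnogram", {
    s <- integer(n)
    s[1] <- sample.int(5L, 1L, prob = config$initial_distribution)
    if (n > 1) {
      for (t in 2:n) s[t] <- sample.int(5L, 1L, prob = tm[s[t - 1], ])
    }
    hypnogram(s - 1L, epoch_seconds = config$epoch_seconds)
  })
}

# Per-epoch spectral amplitude over the two-sided frequency grid of one
# epoch. Each EEG band contributes its stage-specific relative power spread
# uniformly over the band's bins (scaled so the band's time-domain variance
# equals the requested relative power, times the epoch's lognormal jitter);
# the broadband noise floor adds a flat component. Shaping white Gaussian
# noise by this amplitude is frequency-domain filtering, so the band
# processes remain Gaussian. Called inside the night's seeded RNG scope.
epoch_spectral_amps <- function(cfg, ep_len, stage_codes) {
  fs <- cfg$sample_rate_hz
  freqs <- (0:(ep_len - 1)) * fs / ep_len
  freqs <- pmin(freqs, fs - freqs)       # fold to two-sided layout
  edges <- spectral_band_edges()
  n_ep <- length(stage_codes)
  gains <- matrix(cfg$noise_floor, ep_len, n_ep)
  jitter <- if (cfg$band_jitter_sdlog > 0) {
    matrix(exp(stats::rnorm(n_ep * nrow(edges), 0, cfg$band_jitter_sdlog)),
           n_ep, nrow(edges))
  } else {
    matrix(1, n_ep, nrow(edges))
  }
  for (b in seq_len(nrow(edges))) {
    in_band <- freqs >= edges[b, "low"] & freqs < edges[b, "high"]
    nb <- sum(in_band)
    if (nb == 0) next
    per_epoch <- cfg$stage_spectra[stage_codes + 1L, b] * jitter[, b] * ep_len / nb
    gains[in_band, ] <- gains[in_band, ] + rep(per_epoch, each = nb)
  }
  sqrt(gains)
}

#' Simulate single-channel EEG for a hypnogram
#'
#' Each epoch's signal is a sum of band-limited Gaussian processes (delta,
#' theta, alpha, sigma, beta), weighted by the amplitude (square root of
#' relative power) of that epoch's stage profile, plus broadband white noise
#' with variance `noise_floor`. Band processes are generated once for the
#' whole night and modulated per epoch, so spectra change at epoch
#' boundaries exactly as stages do.
#'
#' @param hypnogram A [hypnogram()].
#' @param config A [synthetic_config()]; its `stage_spectra`, `noise_floor`,
#'   `sample_rate_hz` and `seed` are used.
#' @return Numeric vector of length
#'   `n_epochs * epoch_seconds * sample_rate_hz` (arbitrary units).
#' @export
generate_eeg <- function(hypnogram, config) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  validate_synthetic_config(config)
  n_ep <- length(hypnogram)
  if (n_ep == 0L) return(numeric(0))
  present <- sort(unique(as.integer(hypnogram))) + 1L
  tot <- rowSums(config$stage_spectra)[present] + config$noise_floor
  if (any(tot <= 0)) {
    stop("stage(s) ", paste(stage_labels()[present[tot <= 0]], collapse = ", "),
         " are present in the hypnogram but have zero total band power",
         call. = FALSE)
  }
  ep_len <- round(config$epoch_seconds * config$sample_rate_hz)
  n_samples <- n_ep * ep_len
  with_stream_seed(config$seed, "eeg", {
    # one white-noise epoch per column, shaped in the frequency domain by
    # the epoch's spectral amplitude; expected epoch variance = total band
    # power of the stage (jittered) + noise floor
    amps <- epoch_spectral_amps(config, ep_len, as.integer(hypnogram))
    white <- matrix(stats::rnorm(n_samples), ep_len, n_ep)
    spec <- stats::mvfft(white) * amps
    as.vector(Re(stats::mvfft(spec, inverse = TRUE)) / ep_len)
  })
}

#' Simulate a full study night
#'
#' Convenience wrapper: ground-truth hypnogram plus matching EEG.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `hypnogram`, `signal`, and `config`.
#' @export
simulate_night <- function(config) {
  h <- generate_hypnogram(config)
  list(hypnogram = h, signal = generate_eeg(h, config), config = config)
}

#' Read or write a synthetic-study configuration as YAML or JSON
#'
#' @param config A [synthetic_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_synthetic_config` returns a [synthetic_config()].
#' @export
write_synthetic_config <- function(config, path) {
  validate_synthetic_config(config)
  x <- list(
    transition_matrix = apply(config$transition_matrix, 1, as.numeric, simplify = FALSE),
    initial_distribution = as.numeric(config$initial_distribution),
    stage_spectra = apply(config$stage_spectra, 1, as.numeric, simplify = FALSE),
    noise_floor = config$noise_floor,
    band_jitter_sdlog = config$band_jitter_sdlog,
    fragmentation = config$fragmentation,
    sample_rate_hz = config$sample_rate_hz,
    n_epochs = config$n_epochs,
    epoch_seconds = config$epoch_seconds,
    seed = config$seed
  )
  names(x$transition_matrix) <- stage_labels()
  names(x$stage_spectra) <- stage_labels()
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_row_matrix <- function(rows, col_names) {
    m <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(m) <- list(stage_labels(), col_names)
    m
  }
  defaults <- synthetic_config()
  pick <- function(nm, fallback) if (!is.null(x[[nm]])) x[[nm]] else fallback
  synthetic_config(
    transition_matrix = if (!is.null(x$transition_matrix))
      as_row_matrix(x$transition_matrix, stage_labels()) else
        defaults$transition_matrix,
    initial_distribution = pick("initial_distribution", defaults$initial_distribution),
    stage_spectra = if (!is.null(x$stage_spectra))
      as_row_matrix(x$stage_spectra, colnames(defaults$stage_spectra)) else
        defaults$stage_spectra,
    noise_floor = pick("noise_floor", defaults$noise_floor),
    band_jitter_sdlog = pick("band_jitter_sdlog", defaults$band_jitter_sdlog),
    fragmentation = pick("fragmentation", defaults$fragmentation),
    sample_rate_hz = pick("sample_rate_hz", defaults$sample_rate_hz),
    n_epochs = pick("n_epochs", defaults$n_epochs),
    epoch_seconds = pick("epoch_seconds", defaults$epoch_seconds),
    seed = pick("seed", defaults$seed)
  )
}

#' Read and write a single-channel signal as one-column CSV
#'
#' @param x Numeric signal vector.
#' @param path File path.
#' @return `read_signal_csv` returns a numeric vector.
#' @export
write_signal_csv <- function(x, path) {
  utils::write.csv(data.frame(value = x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"value" %in% names(df)) {
    stop("signal CSV must have a 'value' column", call. = FALSE)
  }
  as.numeric(df$value)
}
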