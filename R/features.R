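# Per-epoch time-frequency features: zero-phase bandpass preprocessing and
# multitaper band-power extraction over the classical sleep-EEG bands.

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward then backward (via
#' [signal::filtfilt()]) so the net phase shift is zero; the standard
#' preprocessing for sleep EEG (default passband 0.1-50 Hz).
#'
#' @param x Numeric signal.
#' @param sample_rate_hz Sample rate in Hz.
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sample_rate_hz / 2`.
#' @param order Butterworth order per pass (default 4; effective order is
#'   doubled by the two passes).
#' @return Filtered signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 250)
#' y <- bandpass_zero_phase(sin(2 * pi * 10 * t), 250)
bandpass_zero_phase <- function(x, sample_rate_hz, low_hz = 0.1, high_hz = 50,
                                order = 4) {
  nyq <- sample_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz); got [",
         low_hz, ", ", high_hz, "]", call. = FALSE)
  }
  if (length(x) == 0) return(numeric(0))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

default_feature_bands <- function() {
  matrix(c(0.5, 4, 4, 8, 8, 12, 12, 16, 16, 30, 30, 50), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("low", "high")))
}

band_col_names <- function(band_edges) {
  paste0("band_", band_edges[, 1], "_", band_edges[, 2], "hz")
}

multitaper_psd <- function(x, tapers, fs) {
  # one-sided PSD averaged over tapers; Parseval: sum(psd) * df ~ var(x)
  n <- length(x)
  tx <- tapers * x                       # n x k, recycles x down columns
  spec <- Mod(stats::mvfft(tx))^2 / fs
  k <- ncol(tapers)
  n_freq <- floor(n / 2) + 1
  psd <- rowMeans(spec)[seq_len(n_freq)]
  # fold negative frequencies into the one-sided estimate
  if (n %% 2 == 0) {
    if (n_freq > 2) psd[2:(n_freq - 1)] <- 2 * psd[2:(n_freq - 1)]
  } else {
    if (n_freq > 1) psd[2:n_freq] <- 2 * psd[2:n_freq]
  }
  psd
}

#' Multitaper per-epoch spectral features
#'
#' Splits the signal into non-overlapping 30-s epochs, estimates each
#' epoch's power spectral density with DPSS (Slepian) tapers, integrates
#' the PSD over the requested frequency bands, floors the band powers at a
#' small positive epsilon and returns their log. One feature row per epoch.
#'
#' @param x Numeric signal.
#' @param sample_rate_hz Sample rate in Hz.
#' @param epoch_seconds Epoch duration (default 30 s). A trailing partial
#'   epoch is dropped with a warning.
#' @param band_edges Two-column matrix of band edges in Hz (low, high);
#'   default delta/theta/alpha/sigma/beta/low-gamma:
#'   0.5-4, 4-8, 8-12, 12-16, 16-30, 30-50.
#' @param time_bandwidth DPSS time-bandwidth product (default 4).
#' @param n_tapers Number of tapers (default 7 = 2*4 - 1).
#' @param log_floor Power floor before the log (default 1e-12) so silent
#'   epochs stay finite.
#' @return An object of class `"spectral_features"`: a `T x F` numeric
#'   matrix of log band powers with attributes `band_edges`,
#'   `epoch_seconds` and `sample_rate_hz`.
#' @export
multitaper_epoch_features <- function(x, sample_rate_hz, epoch_seconds = 30,
                                      band_edges = default_feature_bands(),
                                      time_bandwidth = 4, n_tapers = 7,
                                      log_floor = 1e-12) {
  if (n_tapers < 1) stop("n_tapers must be >= 1", call. = FALSE)
  if (n_tapers > 2 * time_bandwidth - 1 + 1e-9) {
    stop("n_tapers = ", n_tapers, " inconsistent with time_bandwidth = ",
         time_bandwidth, " (need n_tapers <= 2*time_bandwidth - 1)",
         call. = FALSE)
  }
  band_edges <- as.matrix(band_edges)
  ep_len <- round(epoch_seconds * sample_rate_hz)
  n_ep <- length(x) %/% ep_len
  if (length(x) %% ep_len != 0) {
    warning("dropping trailing partial epoch (", length(x) %% ep_len,
            " samples)", call. = FALSE)
  }
  tapers <- dpss_tapers(ep_len, time_bandwidth, n_tapers)
  freqs <- (0:(floor(ep_len / 2))) * sample_rate_hz / ep_len
  df <- sample_rate_hz / ep_len
  band_idx <- lapply(seq_len(nrow(band_edges)), function(b) {
    which(freqs >= band_edges[b, 1] & freqs < band_edges[b, 2])
  })
  feats <- matrix(NA_real_, n_ep, nrow(band_edges))
  for (k in seq_len(n_ep)) {
    seg <- x[((k - 1) * ep_len + 1):(k * ep_len)]
    psd <- multitaper_psd(seg - mean(seg), tapers, sample_rate_hz)
    feats[k, ] <- vapply(band_idx, function(ix) sum(psd[ix]) * df, numeric(1))
  }
  feats <- log(pmax(feats, log_floor))
  colnames(feats) <- band_col_names(band_edges)
  structure(feats, band_edges = band_edges, epoch_seconds = epoch_seconds,
            sample_rate_hz = sample_rate_hz, class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat("<spectral_features> ", nrow(x), " epochs x ", ncol(x), " bands\n", sep = "")
  invisible(x)
}

#' Read and write spectral features as CSV
#'
#' Schema: `epoch_index` (0-based) then one column per band, named by the
#' band edges (e.g. `band_0.5_4hz`).
#'
#' @param features A `"spectral_features"` matrix.
#' @param path File path.
#' @return `read_features_csv` returns a `"spectral_features"` object.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(epoch_index = seq_len(nrow(features)) - 1L,
                   unclass(features)[, , drop = FALSE], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"epoch_index" %in% names(df)) {
    stop("features CSV is missing column: epoch_index", call. = FALSE)
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  m <- as.matrix(df[, setdiff(names(df), "epoch_index"), drop = FALSE])
  structure(m, class = "spectral_features")
}
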