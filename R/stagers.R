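# Probabilistic stagers: a KDE-emission hidden Markov model decoded with
# the forward-backward algorithm, and a small MLP classifier (R/mlp.R).
# Both emit a T x 5 posterior matrix over the stages W/REM/N1/N2/N3.

posterior_col_names <- function() paste0("p_", stage_labels())

#' Construct/validate a posterior matrix
#'
#' A posterior matrix holds, for each 30-s epoch, the probability of each
#' of the five sleep stages given all the data and the model. Rows off the
#' probability simplex by at most `tol` (floating-point drift) are
#' renormalized; larger violations are an error.
#'
#' @param probs Numeric `T x 5` matrix.
#' @param tol Maximum tolerated deviation of a row sum from 1 (default 1e-6).
#' @return A `"posterior_matrix"` with columns named `p_W ... p_N3` and
#'   rows summing to 1.
#' @export
posterior_matrix <- function(probs, tol = 1e-6) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 5) stop("posterior matrix must have 5 columns", call. = FALSE)
  if (any(!is.finite(probs))) stop("posterior entries must be finite", call. = FALSE)
  if (any(probs < -tol)) {
    stop("posterior entries must be non-negative", call. = FALSE)
  }
  probs[probs < 0] <- 0
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad)) {
    stop("posterior row(s) off the simplex beyond tolerance ", tol, ": epoch(s) ",
         paste(utils::head(bad, 5) - 1L, collapse = ", "),
         " (row sums ", paste(signif(utils::head(rs[bad], 5), 8), collapse = ", "),
         ")", call. = FALSE)
  }
  probs <- probs / rs
  colnames(probs) <- posterior_col_names()
  structure(probs, class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat("<posterior_matrix> ", nrow(x), " epochs x 5 stages\n", sep = "")
  invisible(x)
}

#' @export
`[.posterior_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, ...]
  out
}

# ---- KDE emissions ---------------------------------------------------------

scott_bandwidth <- function(x) {
  # per-dimension Scott rule: sd_j * n^(-1/(d+4)); degenerate dims get a
  # small positive floor so the kernel stays proper
  n <- nrow(x); d <- ncol(x)
  h <- apply(x, 2, stats::sd) * n^(-1 / (d + 4))
  h[!is.finite(h) | h <= 0] <- 1e-6
  h
}

kde_fit <- function(x, bandwidth = NULL) {
  x <- as.matrix(x)
  h <- if (is.null(bandwidth)) scott_bandwidth(x) else rep_len(bandwidth, ncol(x))
  list(x = x, h = h)
}

log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

kde_logdensity <- function(fit, y) {
  # Gaussian product kernel; evaluated via scaled pairwise distances
  y <- as.matrix(y)
  A <- sweep(y, 2, fit$h, "/")
  B <- sweep(fit$x, 2, fit$h, "/")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  const <- sum(log(fit$h)) + ncol(y) / 2 * log(2 * pi) + log(nrow(fit$x))
  ll <- log_row_sum_exp(-0.5 * pmax(d2, 0)) - const
  pmax(ll, -700)                         # avoid -Inf propagation downstream
}

# ---- HMM stager ------------------------------------------------------------

#' Fit the KDE-emission hidden Markov stager
#'
#' Transition probabilities are label bigram frequencies with add-one
#' pseudocounts (row-normalized); the initial distribution is the smoothed
#' label unigram frequency; each stage's emission density is a Gaussian
#' product-kernel density estimate over that stage's feature rows
#' (per-dimension Scott bandwidth by default). A stage absent from training
#' gets a uniform emission fallback, with a warning.
#'
#' @param features A `T x F` feature matrix (e.g. from
#'   [multitaper_epoch_features()]).
#' @param labels A [hypnogram()] of the same length `T`.
#' @param bandwidth Optional fixed per-dimension kernel bandwidth; default
#'   `NULL` uses Scott's rule per stage.
#' @return An object of class `"hmm_stager"` with elements `transition`,
#'   `initial`, and `emissions` (per-stage KDE fits or `NULL` for the
#'   uniform fallback).
#' @export
fit_hmm <- function(features, labels, bandwidth = NULL) {
  features <- as.matrix(features)
  stopifnot(inherits(labels, "hypnogram"))
  if (nrow(features) != length(labels)) {
    stop("features (", nrow(features), " rows) and labels (", length(labels),
         " epochs) are misaligned", call. = FALSE)
  }
  s <- as.integer(labels) + 1L
  counts <- matrix(1, 5, 5)              # add-one pseudocounts
  if (length(s) > 1) {
    for (t in seq_len(length(s) - 1)) {
      counts[s[t], s[t + 1]] <- counts[s[t], s[t + 1]] + 1
    }
  }
  transition <- counts / rowSums(counts)
  dimnames(transition) <- list(stage_labels(), stage_labels())
  init_counts <- tabulate(s, nbins = 5) + 1
  initial <- stats::setNames(init_counts / sum(init_counts), stage_labels())
  emissions <- vector("list", 5)
  names(emissions) <- stage_labels()
  missing_stages <- character(0)
  for (i in 1:5) {
    rows <- features[s == i, , drop = FALSE]
    if (nrow(rows) == 0) {
      missing_stages <- c(missing_stages, stage_labels()[i])
      emissions[i] <- list(NULL)         # keep slot; uniform fallback
    } else {
      emissions[[i]] <- kde_fit(rows, bandwidth)
    }
  }
  if (length(missing_stages)) {
    warning("stage(s) absent from training data: ",
            paste(missing_stages, collapse = ", "),
            "; using uniform emission fallback", call. = FALSE)
  }
  structure(list(transition = transition, initial = initial,
                 emissions = emissions, n_features = ncol(features)),
            class = "hmm_stager")
}

#' Per-stage emission log-likelihoods of an HMM stager
#'
#' @param model A fitted `"hmm_stager"`.
#' @param features Feature matrix with the training dimensionality.
#' @return A `T x 5` matrix of log-densities (uniform-fallback stages get a
#'   constant 0 column, i.e. density 1, which cancels in normalization).
#' @export
emission_loglik <- function(model, features) {
  stopifnot(inherits(model, "hmm_stager"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop("feature dimensionality (", ncol(features), ") does not match the ",
         "fitted model (", model$n_features, ")", call. = FALSE)
  }
  ll <- matrix(0, nrow(features), 5, dimnames = list(NULL, stage_labels()))
  for (i in 1:5) {
    if (!is.null(model$emissions[[i]])) {
      ll[, i] <- kde_logdensity(model$emissions[[i]], features)
    }
  }
  ll
}

#' Forward-backward smoothing of per-epoch state posteriors
#'
#' Exact smoothed marginals `P(state_t | all epochs)` of a hidden Markov
#' model, computed in the log domain with per-step log-sum-exp so long
#' nights cannot underflow.
#'
#' @param log_likelihoods `T x 5` matrix of per-epoch per-stage emission
#'   log-likelihoods (finite).
#' @param transition 5x5 row-stochastic transition matrix.
#' @param initial Length-5 initial state distribution.
#' @return A [posterior_matrix()] of smoothed marginals.
#' @export
#' @examples
#' ll <- matrix(0, 4, 5)  # uninformative likelihoods
#' fb <- forward_backward(ll, default_transition_matrix(),
#'                        default_initial_distribution())
forward_backward <- function(log_likelihoods, transition, initial) {
  ll <- as.matrix(log_likelihoods)
  if (ncol(ll) != 5) stop("log_likelihoods must have 5 columns", call. = FALSE)
  if (any(!is.finite(ll))) stop("log_likelihoods must be finite", call. = FALSE)
  validate_stochastic_matrix(transition, "transition", tol = 1e-9)
  if (length(initial) != 5 || any(initial < 0) || abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a length-5 probability vector", call. = FALSE)
  }
  T_ <- nrow(ll)
  if (T_ == 0) return(posterior_matrix(matrix(numeric(0), 0, 5)))
  logT <- log(transition)
  logpi <- log(as.numeric(initial))
  la <- matrix(-Inf, T_, 5)
  lb <- matrix(0, T_, 5)
  la[1, ] <- logpi + ll[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      # la[t, j] = logsumexp_i(la[t-1, i] + logT[i, j]) + ll[t, j]
      m <- la[t - 1, ] + logT
      la[t, ] <- log_col_sum_exp(m) + ll[t, ]
    }
    for (t in (T_ - 1):1) {
      # lb[t, i] = logsumexp_j(logT[i, j] + ll[t+1, j] + lb[t+1, j])
      m <- t(logT) + (lb[t + 1, ] + ll[t + 1, ])   # m[j, i]
      lb[t, ] <- log_col_sum_exp(m)
    }
  }
  lg <- la + lb
  lg <- lg - apply(lg, 1, max)
  g <- exp(lg)
  posterior_matrix(g / rowSums(g))
}

log_col_sum_exp <- function(m) {
  # logsumexp down each column of a 5 x 5 (finite or -Inf) matrix
  mx <- apply(m, 2, max)
  out <- mx + log(colSums(exp(sweep(m, 2, mx, "-"))))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Predict stage posteriors from a fitted stager
#'
#' @param model A fitted `"hmm_stager"` or `"mlp_stager"`.
#' @param features Feature matrix.
#' @param ... Unused.
#' @return A [posterior_matrix()].
#' @export
predict_posteriors <- function(model, features, ...) UseMethod("predict_posteriors")

#' @export
predict_posteriors.hmm_stager <- function(model, features, ...) {
  ll <- emission_loglik(model, features)
  forward_backward(ll, model$transition, model$initial)
}

#' Hard hypnogram from posteriors
#'
#' Per-epoch arg-max of the posterior row; ties break toward the lowest
#' stage code (W before REM before N1 ...), deterministically.
#'
#' @param posteriors A [posterior_matrix()].
#' @param epoch_seconds Epoch duration for the returned hypnogram.
#' @return A [hypnogram()].
#' @export
estimate_hypnogram <- function(posteriors, epoch_seconds = 30) {
  m <- unclass(posteriors)
  if (nrow(m) == 0) return(hypnogram(integer(0), epoch_seconds))
  hypnogram(max.col(m, ties.method = "first") - 1L, epoch_seconds = epoch_seconds)
}

#' Read and write posterior matrices as CSV
#'
#' Schema (exact column order): `epoch_index, p_W, p_REM, p_N1, p_N2, p_N3`.
#'
#' @param posteriors A [posterior_matrix()].
#' @param path File path.
#' @return `read_posteriors_csv` returns a [posterior_matrix()].
#' @export
write_posteriors_csv <- function(posteriors, path) {
  m <- unclass(posteriors)
  df <- data.frame(epoch_index = seq_len(nrow(m)) - 1L, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posteriors_csv
#' @export
read_posteriors_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("epoch_index", posterior_col_names())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("posterior CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  posterior_matrix(as.matrix(df[, posterior_col_names(), drop = FALSE]))
}
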