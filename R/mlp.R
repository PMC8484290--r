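# Multilayer-perceptron stager: hidden layers [32, 64, 32], ReLU, 5-way
# softmax head, trained by Adam on the cross-entropy. Implemented with
# plain matrix algebra; the network is small (a few thousand weights on
# six-band features) so base R is entirely adequate and the fit is
# bit-reproducible from its seed.

mlp_init <- function(sizes) {
  # He-style initialization for ReLU layers
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Fit the multilayer-perceptron stager
#'
#' A feed-forward network with hidden layers of size 32, 64 and 32,
#' rectified-linear activations and a five-way softmax output, trained on
#' standardized features with Adam and mini-batch cross-entropy. Features
#' are standardized with training-set statistics, which are stored in the
#' model and re-applied at prediction time.
#'
#' @param features `T x F` feature matrix.
#' @param labels A [hypnogram()] of length `T`; must contain at least two
#'   distinct stages.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param hidden Hidden layer sizes (default `c(32, 64, 32)`).
#' @param epochs Training passes over the data (default 200).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @return An object of class `"mlp_stager"`.
#' @export
fit_mlp <- function(features, labels, seed = 1L, hidden = c(32, 64, 32),
                    epochs = 200, batch_size = 32, learning_rate = 1e-3) {
  X <- as.matrix(features)
  stopifnot(inherits(labels, "hypnogram"))
  if (nrow(X) != length(labels)) {
    stop("features and labels are misaligned", call. = FALSE)
  }
  y <- as.integer(labels) + 1L
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class (",
         stage_label(y[1] - 1L), "); the classifier needs at least two",
         call. = FALSE)
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  Y <- matrix(0, nrow(Xs), 5)
  Y[cbind(seq_along(y), y)] <- 1
  sizes <- c(ncol(Xs), hidden, 5L)
  with_stream_seed(seed, "mlp", {
    par <- mlp_init(sizes)
    L <- length(par$W)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0
    n <- nrow(Xs)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1, n)]
        A <- mlp_forward(par, Xs[idx, , drop = FALSE])
        P <- softmax_rows(A[[L + 1]])
        delta <- (P - Y[idx, , drop = FALSE]) / length(idx)
        step <- step + 1
        for (l in L:1) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- tcrossprod(delta, par$W[[l]]) * (A[[l]] > 0)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          par$W[[l]] <- par$W[[l]] - learning_rate * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          par$b[[l]] <- par$b[[l]] - learning_rate * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    structure(list(par = par, mu = mu, sd = sdv, hidden = hidden, seed = seed),
              class = "mlp_stager")
  })
}

#' @export
predict_posteriors.mlp_stager <- function(model, features, ...) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$mu, "-"), 2, model$sd, "/")
  A <- mlp_forward(model$par, Xs)
  posterior_matrix(softmax_rows(A[[length(A)]]))
}
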