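# Per-epoch uncertainty from posterior rows: the Renyi entropy family
# (Shannon, collision, min-entropy) and the posterior variance, plus the
# 1-bit flagging rule that marks epochs for targeted review.

MAX_ENTROPY_BITS <- log2(5)

validate_simplex <- function(p, tol = 1e-6) {
  if (length(p) != 5) stop("probability vector must have length 5", call. = FALSE)
  if (any(!is.finite(p))) stop("probabilities must be finite", call. = FALSE)
  if (any(p < -tol)) stop("probabilities must be non-negative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop("probabilities must sum to 1 within ", tol, " (got ", signif(s, 8), ")",
         call. = FALSE)
  }
  p <- pmax(p, 0)
  p / sum(p)
}

#' Renyi entropy of a stage-probability vector
#'
#' `S_alpha(p) = log2(sum_i p_i^alpha) / (1 - alpha)`, in bits. The order
#' `alpha` selects the member of the family: `alpha = 1` is the Shannon
#' entropy `-sum p_i log2 p_i` (evaluated with the `0 * log 0 = 0`
#' convention; orders within 1e-9 of 1 are routed to this branch),
#' `alpha = 2` the collision entropy, and `alpha = Inf` the min-entropy
#' `-log2(max p_i)`. For a five-class posterior the value ranges from 0
#' (one stage certain) to `log2(5) = 2.32` bits (all stages equally
#' likely); two equally likely stages give exactly 1 bit, the default
#' review threshold.
#'
#' @param p Length-5 probability vector (renormalized if off the simplex by
#'   at most 1e-6).
#' @param alpha Renyi order, `> 0` or `Inf`.
#' @return Entropy in bits.
#' @export
#' @examples
#' renyi_entropy(c(0, 0, 0, 0.5, 0.5), 1)   # 1 bit: the review threshold case
#' renyi_entropy(rep(0.2, 5), 1)            # 2.32 bits: maximal uncertainty
renyi_entropy <- function(p, alpha) {
  p <- validate_simplex(p)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0) {
    stop("alpha must be a positive scalar (possibly Inf)", call. = FALSE)
  }
  if (is.infinite(alpha)) return(-log2(max(p)))
  if (abs(alpha - 1) < 1e-9) {
    q <- p[p > 0]
    return(-sum(q * log2(q)))
  }
  q <- p[p > 0]                          # 0^alpha terms contribute nothing
  log2(sum(q^alpha)) / (1 - alpha)
}

#' Posterior variance of a stage-probability vector
#'
#' Population variance of the five probability masses,
#' `mean((p_i - 1/5)^2)`: 0 when all stages are equally likely and maximal
#' (0.032) for a one-hot posterior. Note its polarity is opposite to
#' entropy - it measures concentration, not spread - so it is reported as
#' its own measure, never mixed with entropy thresholds.
#'
#' @inheritParams renyi_entropy
#' @return Non-negative scalar.
#' @export
posterior_variance <- function(p) {
  p <- validate_simplex(p)
  mean((p - mean(p))^2)
}

parse_measure <- function(measure) {
  if (is.numeric(measure)) {
    return(list(name = if (is.infinite(measure)) "min" else
      if (abs(measure - 1) < 1e-9) "shannon" else
        if (measure == 2) "collision" else paste0("renyi_", measure),
      alpha = measure))
  }
  switch(tolower(measure),
         shannon = list(name = "shannon", alpha = 1),
         collision = list(name = "collision", alpha = 2),
         min = list(name = "min", alpha = Inf),
         variance = list(name = "variance", alpha = NA_real_),
         stop("unknown uncertainty measure: ", measure,
              " (use 'shannon', 'collision', 'min', 'variance', or a numeric alpha)",
              call. = FALSE))
}

#' Per-epoch uncertainty trace
#'
#' Applies the selected uncertainty measure to every posterior row, giving
#' a time series of per-epoch uncertainty values aligned with the
#' hypnogram.
#'
#' @param posteriors A [posterior_matrix()].
#' @param measure `"shannon"`, `"collision"`, `"min"`, `"variance"`, or a
#'   numeric Renyi order.
#' @return An object of class `"uncertainty_trace"`: a numeric vector (bits
#'   for entropies, variance units otherwise) with attribute `measure`.
#' @export
uncertainty_trace <- function(posteriors, measure = "shannon") {
  m <- unclass(posteriors)
  spec <- parse_measure(measure)
  vals <- vapply(seq_len(nrow(m)), function(t) {
    tryCatch({
      if (spec$name == "variance") posterior_variance(m[t, ])
      else renyi_entropy(m[t, ], spec$alpha)
    }, error = function(e) {
      stop("epoch ", t - 1L, ": ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(1))
  structure(vals, measure = spec$name, alpha = spec$alpha,
            class = "uncertainty_trace")
}

#' @export
print.uncertainty_trace <- function(x, ...) {
  cat("<uncertainty_trace> ", length(x), " epochs, measure = ",
      attr(x, "measure"), "\n", sep = "")
  invisible(x)
}

#' Flag uncertain epochs against a threshold
#'
#' An epoch is flagged for review iff its uncertainty strictly exceeds the
#' threshold; an epoch exactly at the threshold stays automated. The
#' default threshold of 1 bit corresponds to two stages being equally
#' likely and the rest negligible.
#'
#' @param trace An [uncertainty_trace()] (or numeric vector).
#' @param threshold Non-negative scalar, in the trace's units (default 1.0
#'   bit).
#' @return An object of class `"flag_sequence"`: integer 0/1 vector with
#'   attributes `threshold`, `n_flagged` and `burden` (flagged fraction).
#' @export
#' @examples
#' flag_uncertain(c(0.2, 1.2, 1.0))  # only the middle epoch is flagged
flag_uncertain <- function(trace, threshold = 1.0) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a non-negative scalar", call. = FALSE)
  }
  v <- as.numeric(trace)
  if (any(!is.finite(v))) stop("uncertainty trace must be finite", call. = FALSE)
  flags <- as.integer(v > threshold)
  structure(flags, threshold = threshold, n_flagged = sum(flags),
            burden = if (length(flags)) mean(flags) else NA_real_,
            class = "flag_sequence")
}

#' @export
print.flag_sequence <- function(x, ...) {
  cat("<flag_sequence> ", attr(x, "n_flagged"), "/", length(x),
      " epochs flagged (", round(100 * attr(x, "burden"), 1),
      "% burden) at threshold ", attr(x, "threshold"), "\n", sep = "")
  invisible(x)
}

as_flag_sequence <- function(flags, threshold = NA_real_) {
  flags <- as.integer(flags)
  stopifnot(all(flags %in% c(0L, 1L)))
  structure(flags, threshold = threshold, n_flagged = sum(flags),
            burden = if (length(flags)) mean(flags) else NA_real_,
            class = "flag_sequence")
}

#' Write an uncertainty trace (and flags) as CSV with a JSON sidecar
#'
#' CSV schema: `epoch_index, value_bits, flagged`; the sidecar
#' (`<path>.json`) records the measure and threshold.
#'
#' @param trace An [uncertainty_trace()].
#' @param flags A [flag_uncertain()] result aligned with `trace`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, flags, path) {
  check_same_length(trace, flags, what = "trace and flags")
  df <- data.frame(epoch_index = seq_along(trace) - 1L,
                   value_bits = as.numeric(trace),
                   flagged = as.integer(flags))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(measure = attr(trace, "measure"),
               alpha = attr(trace, "alpha"),
               threshold = attr(flags, "threshold"),
               n_flagged = attr(flags, "n_flagged"),
               burden = attr(flags, "burden"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
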