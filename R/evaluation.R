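# Agreement scoring and uncertainty diagnostics: Cohen's Kappa,
# certainty-stratified confusion matrices, entropy-by-correctness
# distribution summaries, and a paired t test across nights.

#' Cohen's Kappa between two hypnograms
#'
#' Chance-corrected agreement `K = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` (fraction of matching epochs) and expected agreement
#' `p_e = sum_i a_i * b_i` over the two raters' marginal stage frequencies.
#' In the degenerate case `p_e = 1` (both raters constant), `K` is 1 when
#' the sequences are identical and 0 otherwise, with a warning.
#'
#' @param a,b [hypnogram()]s (or stage-code vectors) of equal length >= 1.
#' @return An object of class `"kappa_report"`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n_epochs`.
#' @export
#' @examples
#' truth <- hypnogram(c("W", "W", "N2", "N2", "REM"))
#' est <- hypnogram(c("W", "N1", "N2", "N2", "REM"))
#' cohens_kappa(truth, est)
cohens_kappa <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  check_same_length(a, b, what = "hypnograms")
  n <- length(a)
  if (n < 1) stop("hypnograms must contain at least one epoch", call. = FALSE)
  p_o <- mean(a == b)
  ma <- tabulate(a + 1L, nbins = 5) / n
  mb <- tabulate(b + 1L, nbins = 5) / n
  p_e <- sum(ma * mb)
  if (p_e >= 1 - 1e-15) {
    warning("degenerate marginals (expected agreement = 1); kappa set by ",
            "identity convention", call. = FALSE)
    k <- if (p_o == 1) 1 else 0
  } else {
    k <- (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = k, observed_agreement = p_o, expected_agreement = p_e,
                 n_epochs = n), class = "kappa_report")
}

#' @export
print.kappa_report <- function(x, ...) {
  cat(sprintf("Cohen's Kappa: %.3f (p_o = %.3f, p_e = %.3f, n = %d epochs)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n_epochs))
  invisible(x)
}

#' Certainty-stratified confusion matrices
#'
#' Splits epochs into a certain stratum (not flagged) and an uncertain
#' stratum (flagged), and cross-tabulates true stage (rows) against
#' estimated stage (columns) within each, as row percentages. The diagonal
#' of the certain matrix is the per-stage accuracy among confident epochs;
#' the diagonal of the uncertain matrix is the share of flagged epochs the
#' algorithm actually had right (review false alarms). Epochs exactly at
#' the threshold are unflagged by the strict flagging rule and therefore
#' fall in the certain stratum. True stages with no epochs in a stratum
#' yield `NA` rows, not zeros.
#'
#' @param truth,estimate Aligned [hypnogram()]s.
#' @param flags Aligned [flag_uncertain()] result.
#' @return An object of class `"certainty_confusion"`: list with
#'   `certain_matrix`, `uncertain_matrix` (5x5 row percentages),
#'   `certain_counts`, `uncertain_counts`.
#' @export
certainty_confusion <- function(truth, estimate, flags) {
  check_same_length(truth, estimate, flags,
                    what = "truth, estimate and flags")
  tr <- factor(stage_label(as.integer(truth)), levels = stage_labels())
  es <- factor(stage_label(as.integer(estimate)), levels = stage_labels())
  f <- as.integer(flags)
  tab <- function(keep) {
    counts <- table(true = tr[keep], estimate = es[keep])
    counts <- unclass(counts)
    pct <- counts / rowSums(counts) * 100
    pct[rowSums(counts) == 0, ] <- NA_real_
    list(counts = counts, pct = pct)
  }
  cert <- tab(f == 0L)
  unc <- tab(f == 1L)
  structure(list(certain_matrix = cert$pct, uncertain_matrix = unc$pct,
                 certain_counts = cert$counts, uncertain_counts = unc$counts),
            class = "certainty_confusion")
}

#' @export
print.certainty_confusion <- function(x, digits = 0, ...) {
  cat("Certain epochs (row % by true stage):\n")
  print(round(x$certain_matrix, digits))
  cat("Uncertain epochs (row % by true stage):\n")
  print(round(x$uncertain_matrix, digits))
  invisible(x)
}

group_moments <- function(v) {
  n <- length(v)
  if (n == 0) return(list(n = 0L, mean = NA_real_, sd = NA_real_, density = NULL))
  dens <- if (n >= 2 && stats::sd(v) > 0) {
    stats::density(v, from = 0, to = MAX_ENTROPY_BITS)
  } else NULL
  list(n = n, mean = mean(v), sd = sqrt(mean((v - mean(v))^2)), density = dens)
}

#' Entropy distributions by correctness and by true stage
#'
#' Summarizes the per-epoch Shannon-entropy trace of one or more nights:
#' epoch counts, mean and population standard deviation, and a Gaussian
#' kernel-density fit over `[0, log2(5)]` bits, for all epochs and for the
#' correct/incorrect strata, overall and within each true stage.
#'
#' @param trace An [uncertainty_trace()] (bits).
#' @param truth,estimate Aligned [hypnogram()]s; correctness is
#'   `estimate == truth` per epoch.
#' @return An object of class `"entropy_summary"`: list with `overall`
#'   (groups `all`, `correct`, `incorrect`) and `per_stage` (same groups
#'   within each true stage). Standard deviations use the population
#'   convention (divisor `n`).
#' @export
entropy_distribution_summary <- function(trace, truth, estimate) {
  check_same_length(trace, truth, estimate,
                    what = "trace, truth and estimate")
  v <- as.numeric(trace)
  ok <- as.integer(truth) == as.integer(estimate)
  overall <- list(all = group_moments(v),
                  correct = group_moments(v[ok]),
                  incorrect = group_moments(v[!ok]))
  per_stage <- lapply(0:4, function(code) {
    in_stage <- as.integer(truth) == code
    list(all = group_moments(v[in_stage]),
         correct = group_moments(v[in_stage & ok]),
         incorrect = group_moments(v[in_stage & !ok]))
  })
  names(per_stage) <- stage_labels()
  structure(list(overall = overall, per_stage = per_stage,
                 sd_convention = "population"),
            class = "entropy_summary")
}

#' @export
print.entropy_summary <- function(x, ...) {
  fmt <- function(g) {
    if (g$n == 0) "none" else sprintf("%d epochs, %.2f +/- %.2f bits", g$n, g$mean, g$sd)
  }
  cat("Shannon entropy by correctness:\n")
  cat("  all:      ", fmt(x$overall$all), "\n")
  cat("  correct:  ", fmt(x$overall$correct), "\n")
  cat("  incorrect:", fmt(x$overall$incorrect), "\n")
  invisible(x)
}

#' Paired-samples t test on per-night kappas
#'
#' Classic paired t on the differences `a - b` with `n - 1` degrees of
#' freedom and a two-sided p value; the standard comparison of two scoring
#' methods across the same set of nights. Zero-variance differences (e.g.
#' comparing a method with itself) return the `NA` sentinel rather than an
#' infinite statistic.
#'
#' @param kappas_a,kappas_b Numeric vectors of equal length `n >= 2`.
#' @return List with `t`, `df`, `p_value`, `mean_difference`, and
#'   `degenerate` (TRUE when all differences are equal so t is undefined).
#' @export
paired_t_test <- function(kappas_a, kappas_b) {
  check_same_length(kappas_a, kappas_b, what = "kappa vectors")
  n <- length(kappas_a)
  if (n < 2) stop("paired t test needs at least 2 pairs", call. = FALSE)
  d <- as.numeric(kappas_a) - as.numeric(kappas_b)
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = n - 1L, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(kappas_a, kappas_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(d), degenerate = FALSE)
}
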