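# Targeted-review policies: the four scoring methods compared in the
# evaluation - (1) automated, (2) automated + simulated manual review,
# (3) automated + clinically-relevant review, (4) automated + ground-truth
# substitution (the best-case ceiling for any review).

all_stage_pairs <- function() {
  pairs <- utils::combn(stage_labels(), 2, simplify = FALSE)
  lapply(pairs, sort)
}

#' Default clinically relevant stage pairs
#'
#' All 10 unordered stage pairs except \{W, N1\} and \{N1, N2\}: confusions
#' between wake and N1 (and between the light stages N1/N2) are ambiguous
#' even between expert scorers and carry little clinical weight, whereas a
#' confusion such as REM vs N3 is clinically meaningful and worth expert
#' time. A package default, not a clinical standard - always reviewable via
#' the policy object.
#'
#' @return List of sorted length-2 character vectors.
#' @export
default_relevant_pairs <- function() {
  drop <- list(c("N1", "W"), c("N1", "N2"))
  Filter(function(p) !any(vapply(drop, function(d) identical(sort(p), sort(d)),
                                 logical(1))),
         all_stage_pairs())
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs)) return(list())
  pairs <- lapply(pairs, function(p) {
    p <- as.character(p)
    if (length(p) != 2 || anyNA(match(p, stage_labels())) || p[1] == p[2]) {
      stop("relevant pair must be two distinct stage labels; got: ",
           paste(p, collapse = ", "), call. = FALSE)
    }
    sort(p)
  })
  unique(pairs)
}

#' Review policy
#'
#' Bundles the review threshold, the clinically relevant pair set, and the
#' simulated reviewer's skill parameters.
#'
#' @param threshold Entropy threshold in bits (default 1.0).
#' @param relevant_pairs List of unordered stage-label pairs (default
#'   [default_relevant_pairs()]).
#' @param reviewer_accuracy Probability the simulated reviewer corrects a
#'   flagged epoch the algorithm got wrong (default 1 = ideal).
#' @param reviewer_error_rate Probability the reviewer corrupts a flagged
#'   epoch the algorithm had right (default 0 = ideal).
#' @param seed Integer seed for the reviewer's draws.
#' @return An object of class `"review_policy"`.
#' @export
review_policy <- function(threshold = 1.0,
                          relevant_pairs = default_relevant_pairs(),
                          reviewer_accuracy = 1.0,
                          reviewer_error_rate = 0.0,
                          seed = 1L) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  for (p in c(reviewer_accuracy, reviewer_error_rate)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop("reviewer probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(list(threshold = threshold,
                 relevant_pairs = normalize_pairs(relevant_pairs),
                 reviewer_accuracy = reviewer_accuracy,
                 reviewer_error_rate = reviewer_error_rate,
                 seed = as.integer(seed)),
            class = "review_policy")
}

reviewed_hypnogram <- function(stages, method, n_reviewed, epoch_seconds = 30) {
  h <- hypnogram(stages, epoch_seconds)
  attr(h, "method") <- method
  attr(h, "n_reviewed") <- as.integer(n_reviewed)
  class(h) <- c("reviewed_hypnogram", "hypnogram")
  h
}

#' Substitute flagged epochs with ground truth
#'
#' Replaces every flagged epoch of the automated hypnogram with the
#' ground-truth label, leaving unflagged epochs untouched. This is the
#' best-case ceiling of targeted review: it shows the maximum agreement
#' gain any reviewer could deliver at the given flag set.
#'
#' @param automated Automated [hypnogram()].
#' @param flags A [flag_uncertain()] result (or 0/1 vector) of equal length.
#' @param truth Ground-truth [hypnogram()] of equal length.
#' @return A reviewed hypnogram (method `"substitution"`), with attribute
#'   `n_reviewed`.
#' @export
substitute_with_truth <- function(automated, flags, truth) {
  check_same_length(automated, flags, truth,
                    what = "automated, flags and truth")
  s <- as.integer(automated)
  f <- as.integer(flags)
  s[f == 1L] <- as.integer(truth)[f == 1L]
  reviewed_hypnogram(s, "substitution", sum(f),
                     epoch_seconds = attr(automated, "epoch_seconds"))
}

top2_stages <- function(p) {
  # two most probable stages of a posterior row, ties toward lowest code
  ord <- order(-as.numeric(p), seq_along(p))
  stage_labels()[ord[1:2]]
}

#' Restrict flags to clinically relevant confusions
#'
#' A flag survives iff the epoch's two most-probable posterior stages (the
#' stages the decision is effectively between, judged from the information
#' available before any review) form a clinically relevant pair. Output
#' flags are always a subset of input flags, so the review burden can only
#' shrink.
#'
#' @param flags A [flag_uncertain()] result.
#' @param posteriors Aligned [posterior_matrix()].
#' @param relevant_pairs List of unordered stage-label pairs (default
#'   [default_relevant_pairs()]).
#' @return A filtered `"flag_sequence"`.
#' @export
clinically_relevant_filter <- function(flags, posteriors,
                                       relevant_pairs = default_relevant_pairs()) {
  m <- unclass(posteriors)
  check_same_length(flags, seq_len(nrow(m)), what = "flags and posteriors")
  relevant_pairs <- normalize_pairs(relevant_pairs)
  if (length(relevant_pairs) == 0) {
    warning("empty relevant_pairs: all flags removed", call. = FALSE)
  }
  keys <- vapply(relevant_pairs, paste, character(1), collapse = "|")
  out <- as.integer(flags)
  for (t in which(out == 1L)) {
    key <- paste(sort(top2_stages(m[t, ])), collapse = "|")
    if (!key %in% keys) out[t] <- 0L
  }
  as_flag_sequence(out, threshold = attr(flags, "threshold"))
}

#' Simulate an imperfect human reviewer
#'
#' For every flagged epoch: if the automated label disagrees with truth,
#' the reviewer corrects it with probability `reviewer_accuracy`; if it
#' agrees, the reviewer corrupts it to a uniformly random other stage with
#' probability `reviewer_error_rate`. Unflagged epochs are never touched.
#' With a perfect reviewer (accuracy 1, error 0) this reduces exactly to
#' [substitute_with_truth()]. Truth is used only as the simulation oracle;
#' a deployment would put a human here.
#'
#' @param automated Automated [hypnogram()].
#' @param flags Aligned [flag_uncertain()] result.
#' @param truth Aligned ground-truth [hypnogram()].
#' @param policy A [review_policy()]; its `reviewer_accuracy`,
#'   `reviewer_error_rate` and `seed` are used.
#' @return A reviewed hypnogram (method `"manual_review"`).
#' @export
simulate_reviewer <- function(automated, flags, truth, policy = review_policy()) {
  stopifnot(inherits(policy, "review_policy"))
  check_same_length(automated, flags, truth,
                    what = "automated, flags and truth")
  s <- as.integer(automated)
  tr <- as.integer(truth)
  f <- as.integer(flags)
  with_stream_seed(policy$seed, "reviewer", {
    for (t in which(f == 1L)) {
      if (s[t] != tr[t]) {
        if (stats::runif(1) < policy$reviewer_accuracy) s[t] <- tr[t]
      } else if (policy$reviewer_error_rate > 0 &&
                 stats::runif(1) < policy$reviewer_error_rate) {
        s[t] <- sample(setdiff(0:4, s[t]), 1)
      }
    }
  })
  reviewed_hypnogram(s, "manual_review", sum(f),
                     epoch_seconds = attr(automated, "epoch_seconds"))
}

#' Review burden of a flag sequence
#'
#' @param flags A [flag_uncertain()] result (non-empty).
#' @return List with `n_flagged` (count) and `fraction` (share of epochs
#'   targeted for review).
#' @export
#' @examples
#' review_burden(flag_uncertain(c(1.2, 0.3, 1.5, 0.1)))
review_burden <- function(flags) {
  if (length(flags) == 0) stop("flags must be non-empty", call. = FALSE)
  f <- as.integer(flags)
  list(n_flagged = sum(f), fraction = mean(f))
}

#' Apply the four scoring methods to one night
#'
#' Materializes the four hypnograms compared throughout the package:
#' automated, automated + (simulated) manual review, automated +
#' clinically-relevant review, and automated + ground-truth substitution.
#'
#' @param automated Automated [hypnogram()].
#' @param posteriors Aligned [posterior_matrix()].
#' @param truth Aligned ground-truth [hypnogram()].
#' @param policy A [review_policy()].
#' @param measure Uncertainty measure for flagging (default `"shannon"`).
#' @return List with elements `automated`, `review`, `relevant_review`,
#'   `substitution` (hypnograms), plus `flags`, `relevant_flags`, `trace`.
#' @export
apply_review_methods <- function(automated, posteriors, truth,
                                 policy = review_policy(),
                                 measure = "shannon") {
  trace <- uncertainty_trace(posteriors, measure)
  flags <- flag_uncertain(trace, policy$threshold)
  rel_flags <- clinically_relevant_filter(flags, posteriors, policy$relevant_pairs)
  list(
    automated = automated,
    review = simulate_reviewer(automated, flags, truth, policy),
    relevant_review = simulate_reviewer(automated, rel_flags, truth, policy),
    substitution = substitute_with_truth(automated, flags, truth),
    flags = flags,
    relevant_flags = rel_flags,
    trace = trace
  )
}
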