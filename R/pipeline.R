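# End-to-end convenience layer: features for one night, and a simulated
# multi-night cohort study evaluating the four scoring methods.

#' Extract staging features from raw EEG
#'
#' Standard preprocessing chain: zero-phase 0.1-50 Hz bandpass followed by
#' multitaper band-power features per 30-s epoch.
#'
#' @param signal Numeric EEG vector.
#' @param sample_rate_hz Sample rate (default 250).
#' @param low_hz,high_hz Bandpass edges (defaults 0.1 and 50 Hz).
#' @param ... Passed to [multitaper_epoch_features()].
#' @return A `"spectral_features"` matrix.
#' @export
extract_features <- function(signal, sample_rate_hz = 250, low_hz = 0.1,
                             high_hz = 50, ...) {
  filtered <- bandpass_zero_phase(signal, sample_rate_hz, low_hz, high_hz)
  multitaper_epoch_features(filtered, sample_rate_hz, ...)
}

#' Run the four scoring methods on one simulated night
#'
#' Simulates a night, stages it with a fitted model, flags uncertain
#' epochs, applies the four review methods, and scores everything against
#' the simulated ground truth.
#'
#' @param model A fitted stager (`"hmm_stager"` or `"mlp_stager"`).
#' @param config A [synthetic_config()] for the night.
#' @param policy A [review_policy()].
#' @param measure Uncertainty measure for flagging (default `"shannon"`).
#' @return List with the night's `truth`, `posteriors`, `methods` (the
#'   [apply_review_methods()] output), per-method `kappa`, `burden`,
#'   `relevant_burden`, and the night `config`.
#' @export
run_night <- function(model, config, policy = review_policy(),
                      measure = "shannon") {
  night <- simulate_night(config)
  feats <- extract_features(night$signal, config$sample_rate_hz,
                            epoch_seconds = config$epoch_seconds)
  post <- predict_posteriors(model, feats)
  automated <- estimate_hypnogram(post, config$epoch_seconds)
  methods <- apply_review_methods(automated, post, night$hypnogram,
                                  policy = policy, measure = measure)
  kappa <- vapply(methods[c("automated", "review", "relevant_review",
                            "substitution")],
                  function(h) cohens_kappa(night$hypnogram, h)$kappa,
                  numeric(1))
  list(truth = night$hypnogram,
       posteriors = post,
       methods = methods,
       kappa = kappa,
       burden = review_burden(methods$flags)$fraction,
       relevant_burden = review_burden(methods$relevant_flags)$fraction,
       config = config)
}

#' Simulate and evaluate a multi-night cohort study
#'
#' Mirrors a train/test cohort design: training nights spanning the
#' severity range are simulated and pooled to fit the stager; each test
#' night is then staged, flagged, reviewed under all four methods, and
#' scored against its ground truth. Test-night fragmentation defaults span
#' healthy to severe, so review burden and agreement vary across nights as
#' they do across a clinical cohort.
#'
#' @param n_nights Number of test nights (default 10).
#' @param seed Global seed; every night and the reviewer derive their own
#'   seeds from it.
#' @param stager `"hmm"` or `"mlp"`.
#' @param n_epochs Epochs per night (default 960).
#' @param train_fragmentation Fragmentation of the training nights
#'   (default one night each at 0, 0.15, 0.3, 0.5).
#' @param test_fragmentation Length-`n_nights` fragmentation vector;
#'   default spans 0 to 0.5 over the cohort.
#' @param policy A [review_policy()]; its seed is re-derived per night.
#' @param measure Uncertainty measure (default `"shannon"`).
#' @return An object of class `"cohort_study"`: list with `model`,
#'   `nights` (per-night results of [run_night()]), and `kappa` (an
#'   `n_nights x 4` matrix of per-night kappas by method).
#' @export
run_cohort <- function(n_nights = 10, seed = 1L, stager = c("hmm", "mlp"),
                       n_epochs = 960,
                       train_fragmentation = c(0, 0.15, 0.3, 0.5),
                       test_fragmentation = NULL,
                       policy = review_policy(),
                       measure = "shannon") {
  stager <- match.arg(stager)
  if (is.null(test_fragmentation)) {
    test_fragmentation <- seq(0, 0.5, length.out = n_nights)
  }
  if (length(test_fragmentation) != n_nights) {
    stop("test_fragmentation must have length n_nights", call. = FALSE)
  }
  train <- lapply(seq_along(train_fragmentation), function(i) {
    cfg <- synthetic_config(n_epochs = n_epochs,
                            fragmentation = train_fragmentation[i],
                            seed = derive_seed(seed, paste0("train", i)))
    night <- simulate_night(cfg)
    list(features = extract_features(night$signal, cfg$sample_rate_hz),
         labels = night$hypnogram)
  })
  feats <- do.call(rbind, lapply(train, function(x) unclass(x$features)))
  labels <- hypnogram(unlist(lapply(train, function(x) as.integer(x$labels))))
  model <- if (stager == "hmm") {
    fit_hmm(feats, labels)
  } else {
    fit_mlp(feats, labels, seed = derive_seed(seed, "mlp_fit"))
  }
  nights <- lapply(seq_len(n_nights), function(i) {
    cfg <- synthetic_config(n_epochs = n_epochs,
                            fragmentation = test_fragmentation[i],
                            seed = derive_seed(seed, paste0("test", i)))
    night_policy <- review_policy(threshold = policy$threshold,
                                  relevant_pairs = policy$relevant_pairs,
                                  reviewer_accuracy = policy$reviewer_accuracy,
                                  reviewer_error_rate = policy$reviewer_error_rate,
                                  seed = derive_seed(seed, paste0("review", i)))
    run_night(model, cfg, policy = night_policy, measure = measure)
  })
  kappa <- t(vapply(nights, function(x) x$kappa, numeric(4)))
  colnames(kappa) <- c("automated", "review", "relevant_review", "substitution")
  structure(list(model = model, nights = nights, kappa = kappa, seed = seed),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat("<cohort_study> ", nrow(x$kappa), " test nights\n", sep = "")
  cat("Median Cohen's Kappa by scoring method:\n")
  print(round(apply(x$kappa, 2, stats::median), 3))
  burdens <- vapply(x$nights, function(n) n$burden, numeric(1))
  cat(sprintf("Review burden: %.0f%% - %.0f%% of epochs (median %.0f%%)\n",
              100 * min(burdens), 100 * max(burdens),
              100 * stats::median(burdens)))
  invisible(x)
}

#' Pooled evaluation summary of a cohort study
#'
#' Concatenates all test nights and computes the pooled uncertainty
#' diagnostics: entropy-by-correctness summary, certainty-stratified
#' confusion matrices, per-night kappas and burdens, and the paired t test
#' of substitution vs automated scoring.
#'
#' @param study A [run_cohort()] result.
#' @return List with `kappa` (matrix), `burden`, `relevant_burden`,
#'   `entropy_summary`, `confusion`, and `t_test`.
#' @export
summarize_cohort <- function(study) {
  stopifnot(inherits(study, "cohort_study"))
  truth <- hypnogram(unlist(lapply(study$nights,
                                   function(n) as.integer(n$truth))))
  automated <- hypnogram(unlist(lapply(study$nights,
                                       function(n) as.integer(n$methods$automated))))
  trace <- structure(unlist(lapply(study$nights,
                                   function(n) as.numeric(n$methods$trace))),
                     measure = "shannon", alpha = 1,
                     class = "uncertainty_trace")
  flags <- as_flag_sequence(unlist(lapply(study$nights,
                                          function(n) as.integer(n$methods$flags))),
                            threshold = attr(study$nights[[1]]$methods$flags,
                                             "threshold"))
  list(
    kappa = study$kappa,
    burden = vapply(study$nights, function(n) n$burden, numeric(1)),
    relevant_burden = vapply(study$nights, function(n) n$relevant_burden,
                             numeric(1)),
    entropy_summary = entropy_distribution_summary(trace, truth, automated),
    confusion = certainty_confusion(truth, automated, flags),
    t_test = paired_t_test(study$kappa[, "substitution"],
                           study$kappa[, "automated"])
  )
}
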