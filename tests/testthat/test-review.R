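test_that("default relevant pairs exclude the hard-to-score light-sleep confusions", {
  pairs <- default_relevant_pairs()
  keys <- sapply(pairs, paste, collapse = "|")
  expect_length(pairs, 8)
  expect_false("N1|W" %in% keys)
  expect_false("N1|N2" %in% keys)
  expect_true("N3|REM" %in% keys)
})

test_that("review policy validates probabilities and pair sets", {
  expect_error(review_policy(reviewer_accuracy = 1.4), "\\[0, 1\\]")
  expect_error(review_policy(threshold = -1), "non-negative")
  expect_error(review_policy(relevant_pairs = list(c("W", "W"))), "distinct")
  p <- review_policy(relevant_pairs = list(c("N3", "REM"), c("REM", "N3")))
  expect_length(p$relevant_pairs, 1)
})

test_that("substitution replaces exactly the flagged epochs with truth", {
  automated <- hypnogram(c("W", "W", "N2"))
  truth <- hypnogram(c("N1", "W", "N2"))
  out <- substitute_with_truth(automated, c(1L, 0L, 0L), truth)
  expect_identical(stage_label(as.integer(out)), c("N1", "W", "N2"))
  expect_identical(attr(out, "n_reviewed"), 1L)
  no_flags <- substitute_with_truth(automated, rep(0L, 3), truth)
  expect_identical(as.integer(no_flags), as.integer(automated))
  all_flags <- substitute_with_truth(automated, rep(1L, 3), truth)
  expect_identical(as.integer(all_flags), as.integer(truth))
  expect_equal(cohens_kappa(all_flags, truth)$kappa, 1)
  expect_error(substitute_with_truth(automated, c(1L, 0L), truth),
               "equal lengths")
})

test_that("substitution never lowers per-epoch accuracy (random instances)", {
  set.seed(17)
  for (i in 1:50) {
    T_ <- sample(20:60, 1)
    automated <- hypnogram(sample(0:4, T_, replace = TRUE))
    truth <- hypnogram(sample(0:4, T_, replace = TRUE))
    flags <- sample(0:1, T_, replace = TRUE)
    out <- substitute_with_truth(automated, flags, truth)
    acc_before <- mean(as.integer(automated) == as.integer(truth))
    acc_after <- mean(as.integer(out) == as.integer(truth))
    expect_gte(acc_after, acc_before)
  }
})

test_that("clinically relevant filtering keeps REM-vs-N3 flags and drops W-vs-N1 flags", {
  post <- posterior_matrix(rbind(
    c(0.45, 0.02, 0.50, 0.02, 0.01),   # top-2 {W, N1}: not relevant
    c(0.02, 0.50, 0.02, 0.01, 0.45),   # top-2 {REM, N3}: relevant
    c(0.02, 0.50, 0.02, 0.01, 0.45)))  # relevant but unflagged
  flags <- as_flag_sequence(c(1L, 1L, 0L))
  out <- clinically_relevant_filter(flags, post)
  expect_identical(as.integer(out), c(0L, 1L, 0L))
  # subset contract on random flag sets
  set.seed(41)
  rnd <- posterior_matrix(t(replicate(40, random_simplex())))
  f <- as_flag_sequence(sample(0:1, 40, replace = TRUE))
  filtered <- clinically_relevant_filter(f, rnd)
  expect_true(all(as.integer(filtered) <= as.integer(f)))
  expect_warning(none <- clinically_relevant_filter(f, rnd, list()),
                 "empty relevant_pairs")
  expect_identical(sum(as.integer(none)), 0L)
})

test_that("the ideal reviewer equals substitution and the inert reviewer is a no-op", {
  set.seed(23)
  T_ <- 60
  automated <- hypnogram(sample(0:4, T_, replace = TRUE))
  truth <- hypnogram(sample(0:4, T_, replace = TRUE))
  flags <- as_flag_sequence(sample(0:1, T_, replace = TRUE))
  ideal <- simulate_reviewer(automated, flags, truth,
                             review_policy(reviewer_accuracy = 1,
                                           reviewer_error_rate = 0, seed = 5))
  expect_identical(as.integer(ideal),
                   as.integer(substitute_with_truth(automated, flags, truth)))
  inert <- simulate_reviewer(automated, flags, truth,
                             review_policy(reviewer_accuracy = 0,
                                           reviewer_error_rate = 0, seed = 5))
  expect_identical(as.integer(inert), as.integer(automated))
})

test_that("reviewer corrections follow the stated binomial rates", {
  n <- 10000
  automated <- hypnogram(rep(0L, n))      # always wrong (truth is REM)
  truth <- hypnogram(rep(1L, n))
  flags <- as_flag_sequence(rep(1L, n))
  out <- simulate_reviewer(automated, flags, truth,
                           review_policy(reviewer_accuracy = 0.8,
                                         reviewer_error_rate = 0.1,
                                         seed = 314))
  corrected <- mean(as.integer(out) == 1L)
  expect_lt(abs(corrected - 0.8), 0.01)
  # flagged-correct epochs get corrupted at the error rate
  automated2 <- truth
  out2 <- simulate_reviewer(automated2, flags, truth,
                            review_policy(reviewer_accuracy = 0.8,
                                          reviewer_error_rate = 0.1,
                                          seed = 314))
  expect_lt(abs(mean(as.integer(out2) != 1L) - 0.1), 0.01)
})

test_that("an error-prone reviewer can lower agreement below the automated score", {
  set.seed(73)
  truth <- hypnogram(sample(0:4, 500, replace = TRUE, prob = c(3, 1, 1, 3, 1)))
  automated <- truth                       # strong automated scoring
  flags <- as_flag_sequence(sample(0:1, 500, replace = TRUE, prob = c(0.5, 0.5)))
  sloppy <- simulate_reviewer(automated, flags, truth,
                              review_policy(reviewer_accuracy = 0.5,
                                            reviewer_error_rate = 0.5,
                                            seed = 8))
  k_auto <- cohens_kappa(truth, automated)$kappa
  k_rev <- cohens_kappa(truth, sloppy)$kappa
  expect_lt(k_rev, k_auto)
})

test_that("review burden reports count and fraction", {
  expect_equal(review_burden(as_flag_sequence(c(1L, 0L, 1L, 0L))),
               list(n_flagged = 2L, fraction = 0.5))
  expect_equal(review_burden(as_flag_sequence(rep(0L, 10))),
               list(n_flagged = 0L, fraction = 0))
  flags <- as_flag_sequence(c(rep(1L, 123), rep(0L, 683 - 123)))
  expect_equal(round(review_burden(flags)$fraction, 2), 0.18)
  expect_error(review_burden(as_flag_sequence(integer(0))), "non-empty")
})
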