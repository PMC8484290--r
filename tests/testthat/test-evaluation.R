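test_that("Cohen's kappa matches hand-evaluated cases", {
  h <- hypnogram(sample(0:4, 30, replace = TRUE))
  expect_equal(cohens_kappa(h, h)$kappa, 1)
  a <- hypnogram(rep(0L, 20)); b <- hypnogram(rep(2L, 20))
  k0 <- cohens_kappa(a, b)
  expect_equal(k0$kappa, 0)
  expect_equal(k0$observed_agreement, 0)
  expect_equal(k0$expected_agreement, 0)
  # two-class toy with agreement table [[20, 5], [10, 15]], T = 50:
  # p_o = 35/50 = 0.7; marginals a = (0.5, 0.5), b = (0.6, 0.4); p_e = 0.5
  a2 <- hypnogram(c(rep(0L, 25), rep(3L, 25)))
  b2 <- hypnogram(c(rep(0L, 20), rep(3L, 5), rep(0L, 10), rep(3L, 15)))
  k <- cohens_kappa(a2, b2)
  expect_equal(k$observed_agreement, 0.7, tolerance = 1e-12)
  expect_equal(k$expected_agreement, 0.5, tolerance = 1e-12)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_error(cohens_kappa(a, hypnogram(0L)), "equal lengths")
})

test_that("kappa is symmetric, bounded by 1, and degenerate cases warn", {
  set.seed(19)
  for (i in 1:25) {
    a <- hypnogram(sample(0:4, 40, replace = TRUE))
    b <- hypnogram(sample(0:4, 40, replace = TRUE))
    kab <- cohens_kappa(a, b)$kappa
    expect_equal(kab, cohens_kappa(b, a)$kappa, tolerance = 1e-12)
    expect_lte(kab, 1)
  }
  const <- hypnogram(rep(2L, 10))
  expect_warning(k_same <- cohens_kappa(const, const)$kappa, "degenerate")
  expect_equal(k_same, 1)
})

test_that("kappa agrees with an independent implementation on random pairs", {
  skip_if_not_installed("e1071")
  set.seed(29)
  for (i in 1:20) {
    a <- sample(0:4, 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.6, a, sample(0:4, 200, replace = TRUE))
    tab <- table(factor(a, levels = 0:4), factor(b, levels = 0:4))
    ref <- e1071::classAgreement(tab)$kappa
    expect_equal(cohens_kappa(hypnogram(a), hypnogram(b))$kappa, ref,
                 tolerance = 1e-10)
  }
})

test_that("certainty confusion matrices stratify by flag and tabulate row percentages", {
  truth <- hypnogram(c("W", "W", "W", "REM", "REM", "N1", "N2", "N2", "N3", "N3"))
  est <- hypnogram(c("W", "W", "N1", "REM", "W", "N1", "N2", "N3", "N3", "N3"))
  flags <- as_flag_sequence(c(0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))
  cc <- certainty_confusion(truth, est, flags)
  # certain stratum: W epochs 1,2 both scored W -> 100% diagonal
  expect_equal(cc$certain_matrix["W", "W"], 100)
  expect_equal(cc$certain_matrix["N3", "N3"], 100)
  # uncertain stratum: one W epoch scored N1, one REM scored W, one N2 scored N3
  expect_equal(cc$uncertain_matrix["W", "N1"], 100)
  expect_equal(cc$uncertain_matrix["REM", "W"], 100)
  expect_equal(cc$uncertain_matrix["N2", "N3"], 100)
  # empty rows are NA, not zero
  expect_true(all(is.na(cc$uncertain_matrix["N3", ])))
  # counts across both strata partition all epochs
  expect_equal(sum(cc$certain_counts) + sum(cc$uncertain_counts), 10)
  # populated rows sum to 100
  pops <- rowSums(cc$certain_counts) > 0
  expect_equal(unname(rowSums(cc$certain_matrix[pops, , drop = FALSE])),
               rep(100, sum(pops)), tolerance = 1e-9)
})

test_that("perfect unflagged estimates give a 100% diagonal and an empty uncertain stratum", {
  truth <- hypnogram(rep(0:4, each = 4))
  cc <- certainty_confusion(truth, truth, as_flag_sequence(rep(0L, 20)))
  expect_equal(unname(diag(cc$certain_matrix)), rep(100, 5))
  expect_true(all(is.na(cc$uncertain_matrix)))
})

test_that("confusion matrices are invariant to epoch order", {
  set.seed(47)
  truth <- hypnogram(sample(0:4, 100, replace = TRUE))
  est <- hypnogram(sample(0:4, 100, replace = TRUE))
  flags <- as_flag_sequence(sample(0:1, 100, replace = TRUE))
  perm <- sample(100)
  cc1 <- certainty_confusion(truth, est, flags)
  cc2 <- certainty_confusion(truth[perm], est[perm],
                             as_flag_sequence(as.integer(flags)[perm]))
  expect_equal(cc1$certain_matrix, cc2$certain_matrix)
  expect_equal(cc1$uncertain_matrix, cc2$uncertain_matrix)
})

test_that("entropy summaries report population moments by correctness group", {
  trace <- structure(c(0.1, 0.9, 1.5), measure = "shannon",
                     class = "uncertainty_trace")
  truth <- hypnogram(c(0L, 1L, 2L))
  est <- hypnogram(c(0L, 1L, 3L))        # correctness 1, 1, 0
  es <- entropy_distribution_summary(trace, truth, est)
  expect_equal(es$overall$correct$n + es$overall$incorrect$n,
               es$overall$all$n)
  expect_equal(es$overall$correct$mean, 0.5, tolerance = 1e-12)
  expect_equal(es$overall$correct$sd, 0.4, tolerance = 1e-12)  # population sd
  expect_equal(es$overall$incorrect$n, 1L)
  # all-correct, all-zero-entropy edge: zero moments, empty incorrect group
  zero <- structure(rep(0, 4), measure = "shannon",
                    class = "uncertainty_trace")
  h4 <- hypnogram(rep(3L, 4))
  es0 <- entropy_distribution_summary(zero, h4, h4)
  expect_equal(es0$overall$correct$mean, 0)
  expect_equal(es0$overall$correct$sd, 0)
  expect_equal(es0$overall$incorrect$n, 0L)
  expect_true(is.na(es0$overall$incorrect$mean))
  # per-stage groups are keyed on the true stage
  expect_equal(es$per_stage$N1$all$n, 1L)
  expect_equal(es$per_stage$N1$incorrect$n, 1L)
})

test_that("paired t test matches hand evaluation and handles degeneracy", {
  res <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)   # 3.4641
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-res$t, 2), tolerance = 1e-12)
  swapped <- paired_t_test(c(1, 1, 1), c(2, 3, 4))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)
  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_true(same$degenerate)
  expect_true(is.na(same$t))
  expect_error(paired_t_test(1, 1), "at least 2")
})
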