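test_that("forward-backward reduces to normalized initial x likelihood at T = 1", {
  ll <- matrix(log(c(0.1, 0.4, 0.2, 0.2, 0.1)), 1, 5)
  init <- c(0.5, 0.1, 0.1, 0.1, 0.2)
  post <- forward_backward(ll, default_transition_matrix(), init)
  expected <- exp(ll[1, ]) * init
  expect_equal(as.numeric(post[1, ]), expected / sum(expected),
               tolerance = 1e-12)
})

test_that("uniform everything gives uniform smoothed marginals", {
  post <- forward_backward(matrix(0, 7, 5), matrix(0.2, 5, 5), rep(0.2, 5))
  expect_equal(unclass(post), matrix(0.2, 7, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("forward-backward matches exhaustive path enumeration on random models", {
  set.seed(2024)
  worst <- 0
  for (rep in 1:100) {
    T_ <- sample(1:5, 1)
    trans <- random_stochastic_matrix()
    init <- random_simplex()
    ll <- matrix(log(runif(T_ * 5, 0.05, 1)), T_, 5)
    post <- forward_backward(ll, trans, init)
    oracle <- brute_force_marginals(ll, trans, init)
    worst <- max(worst, max(abs(unclass(post) - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("forward-backward rejects malformed inputs", {
  ll <- matrix(0, 3, 5)
  bad <- default_transition_matrix(); bad[2, ] <- 0
  expect_error(forward_backward(ll, bad, rep(0.2, 5)), "row")
  expect_error(forward_backward(matrix(-Inf, 3, 5),
                                default_transition_matrix(), rep(0.2, 5)),
               "finite")
})

test_that("transition estimates are pseudocount-smoothed bigram frequencies", {
  feats <- matrix(rnorm(100 * 2), 100, 2)
  m <- suppressWarnings(fit_hmm(feats, hypnogram(rep(3L, 100))))
  # hand count: 99 N2->N2 bigrams + 1 pseudocount over a row total of 103
  expect_equal(m$transition["N2", "N2"], 100 / 104, tolerance = 1e-12)
  expect_equal(m$transition["N2", "W"], 1 / 104, tolerance = 1e-12)
  expect_true(all(m$transition["N2", "N2"] > m$transition["N2", -4]))
  # rows never seen are uniform from pseudocounts alone
  expect_equal(unname(m$transition["W", ]), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sum(m$initial), 1, tolerance = 1e-12)
})

test_that("single-epoch training yields a valid pseudocount-dominated model", {
  m <- suppressWarnings(fit_hmm(matrix(0, 1, 3), hypnogram(2L)))
  expect_equal(unname(m$transition), matrix(0.2, 5, 5), tolerance = 1e-12)
  expect_equal(rowSums(m$transition), rep(1, 5), ignore_attr = TRUE)
})

test_that("per-stage KDEs put more density on their own cluster than the other's", {
  set.seed(88)
  c1 <- matrix(rnorm(200 * 2, mean = 0), 200, 2)
  c2 <- matrix(rnorm(200 * 2, mean = 6), 200, 2)
  labels <- hypnogram(rep(c(0L, 3L), each = 200))
  m <- suppressWarnings(fit_hmm(rbind(c1, c2), labels))
  ll <- emission_loglik(m, rbind(colMeans(c1), colMeans(c2)))
  expect_gt(ll[1, 1], ll[1, 4])  # W density higher at W centroid
  expect_gt(ll[2, 4], ll[2, 1])  # N2 density higher at N2 centroid
})

test_that("misaligned features and labels are rejected with both sizes named", {
  expect_error(fit_hmm(matrix(0, 10, 2), hypnogram(rep(0L, 9))),
               "10.*9")
})

test_that("hypnogram estimation is arg-max with ties toward the lowest stage code", {
  post <- posterior_matrix(rbind(c(0.1, 0.6, 0.1, 0.1, 0.1),
                                 c(0.5, 0.5, 0, 0, 0),
                                 c(0.2, 0.2, 0.2, 0.2, 0.2)))
  h <- estimate_hypnogram(post)
  expect_identical(as.integer(h), c(1L, 0L, 0L))
  one_hot <- diag(5)[c(3, 1, 5, 2), ]
  expect_identical(as.integer(estimate_hypnogram(posterior_matrix(one_hot))),
                   c(2L, 0L, 4L, 1L))
})

test_that("posterior matrix validation renormalizes drift but rejects gross violations", {
  m <- matrix(0.2, 2, 5) + 1e-8
  expect_equal(rowSums(unclass(posterior_matrix(m))), c(1, 1),
               tolerance = 1e-15)
  expect_error(posterior_matrix(matrix(0.3, 2, 5)), "off the simplex")
  expect_error(posterior_matrix(matrix(c(-0.2, 0.3, 0.3, 0.3, 0.3), 1, 5)),
               "non-negative")
})

test_that("MLP posteriors lie on the simplex and training is seed-deterministic", {
  set.seed(55)
  X <- rbind(matrix(rnorm(100 * 3), 100, 3),
             matrix(rnorm(100 * 3, mean = 4), 100, 3))
  y <- hypnogram(rep(c(0L, 3L), each = 100))
  m1 <- fit_mlp(X, y, seed = 9, epochs = 60)
  m2 <- fit_mlp(X, y, seed = 9, epochs = 60)
  p1 <- predict_posteriors(m1, X)
  p2 <- predict_posteriors(m2, X)
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-12)
  expect_equal(rowSums(unclass(p1)), rep(1, 200), tolerance = 1e-6)
  expect_error(fit_mlp(X, hypnogram(rep(0L, 200)), seed = 1),
               "single class")
})

test_that("MLP separates linearly separable two-cluster data", {
  set.seed(77)
  X <- rbind(matrix(rnorm(100 * 2, mean = -2), 100, 2),
             matrix(rnorm(100 * 2, mean = 2), 100, 2))
  y <- hypnogram(rep(c(1L, 4L), each = 100))
  m <- fit_mlp(X, y, seed = 4, epochs = 100)
  pred <- estimate_hypnogram(predict_posteriors(m, X))
  expect_gte(mean(as.integer(pred) == as.integer(y)), 0.95)
})

test_that("HMM smoothing beats transition-free naive Bayes on a diagonal chain", {
  night <- quick_night(n_epochs = 400, seed = 60, jitter = 0.8)
  held <- quick_night(n_epochs = 400, seed = 61, jitter = 0.8)
  ftr <- quick_features(night)
  fte <- quick_features(held)
  m <- fit_hmm(ftr, night$hypnogram)
  truth <- as.integer(held$hypnogram)
  fb_acc <- mean(as.integer(estimate_hypnogram(predict_posteriors(m, fte))) ==
                   truth)
  ll <- emission_loglik(m, fte)
  nb <- max.col(sweep(ll, 2, log(m$initial), "+"), ties.method = "first") - 1L
  nb_acc <- mean(nb == truth)
  expect_gt(fb_acc, nb_acc)
})

test_that("a stager trained on one night recovers held-out stages well above chance", {
  night <- quick_night(n_epochs = 150, seed = 70, jitter = 0)
  held <- quick_night(n_epochs = 150, seed = 71, jitter = 0)
  m <- fit_hmm(quick_features(night), night$hypnogram)
  pred <- estimate_hypnogram(predict_posteriors(m, quick_features(held)))
  expect_gt(mean(as.integer(pred) == as.integer(held$hypnogram)), 0.6)
})

test_that("posteriors CSV round-trips with the mandated column order", {
  set.seed(31)
  post <- posterior_matrix(t(replicate(10, random_simplex())))
  path <- withr::local_tempfile(fileext = ".csv")
  write_posteriors_csv(post, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("epoch_index", "p_W", "p_REM", "p_N1", "p_N2", "p_N3"))
  expect_equal(unclass(read_posteriors_csv(path)), unclass(post),
               tolerance = 1e-10, ignore_attr = TRUE)
})
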