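test_that("EM fits mixtures with sane posteriors and seeded determinism", {
  set.seed(42)
  X <- matrix(c(rnorm(100, 0), rnorm(100, 10)), ncol = 1)

  # K = 1: trivial posterior and weights
  f1 <- fit_em(X, 1, seed = 1)
  expect_equal(unname(f1$model$weights), 1)
  expect_true(all(f1$assignment$posterior == 1))

  # two well-separated blobs: labels reproduce blob membership
  f2 <- fit_em(X, 2, seed = 1)
  planted <- rep(1:2, each = 100)
  expect_equal(partition_metrics(f2$assignment$labels, planted)$rand, 1.0)

  # posterior rows sum to 1; labels are the posterior argmax
  expect_equal(rowSums(f2$assignment$posterior), rep(1, 200),
               tolerance = 1e-9)
  expect_equal(f2$assignment$labels,
               max.col(f2$assignment$posterior, ties.method = "first"))
  expect_equal(sum(f2$model$weights), 1, tolerance = 1e-9)

  # same data, same seed: identical labels
  f2b <- fit_em(X, 2, seed = 1)
  expect_identical(f2$assignment$labels, f2b$assignment$labels)
})

test_that("maximum-likelihood EM has a non-decreasing log-likelihood trace", {
  set.seed(7)
  X <- cbind(c(rnorm(60, 0), rnorm(60, 6)),
             c(rnorm(60, 0), rnorm(60, -4)))
  for (K in 2:3) {
    fit <- fit_em(X, K, seed = 3, var_prior = 0, var_floor_frac = 0)
    trace <- fit$model$ll_trace
    expect_gt(length(trace), 1)
    expect_true(all(diff(trace) >= -1e-7 * abs(trace[-length(trace)])))
  }
})

test_that("EM agrees with an independent mixture implementation on blobs", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(11)
  X <- cbind(c(rnorm(80, 0), rnorm(80, 8)), c(rnorm(80, 0), rnorm(80, 8)))
  ours <- fit_em(X, 2, seed = 1)$assignment$labels
  theirs <- Mclust(X, G = 2, modelNames = "VVI",
                   verbose = FALSE)$classification
  expect_equal(partition_metrics(ours, theirs)$rand, 1.0)
})

test_that("cross-validated forward search picks one component for one blob", {
  set.seed(5)
  X <- matrix(rnorm(300, 0, 1), ncol = 3)
  sel <- select_k(X, k_max = 4, folds = 5, seed = 1)
  expect_equal(sel$k, 1L)
  expect_equal(nrow(sel$cv_table), 2L)  # stopped at the first non-improvement
})

test_that("cross-validated forward search finds well-separated blob counts", {
  set.seed(9)
  X <- cbind(c(rnorm(70, 0), rnorm(70, 12), rnorm(70, -12)),
             c(rnorm(70, 0), rnorm(70, 12), rnorm(70, 12)))
  sel <- select_k(X, k_max = 6, folds = 5, seed = 2)
  expect_equal(sel$k, 3L)
})

test_that("partition metrics match hand-derived pair counts", {
  # identical partitions
  m <- partition_metrics(c(1, 1, 2, 2), c(5, 5, 9, 9))
  expect_equal(unlist(m), c(rand = 1, jaccard = 1, fm = 1))

  # a=1 b=2 c=1 d=2
  m2 <- partition_metrics(c(1, 1, 2, 2), c(1, 1, 1, 2))
  expect_equal(m2$rand, 0.5)
  expect_equal(m2$jaccard, 0.25)
  expect_equal(m2$fm, 1 / sqrt(6), tolerance = 1e-4)

  # all singletons vs one cluster: a = 0
  m3 <- partition_metrics(1:4, rep(1, 4))
  expect_equal(unlist(m3), c(rand = 0, jaccard = 0, fm = 0))

  expect_error(partition_metrics(1:3, 1:4), "length")
})

test_that("partition metrics are invariant to relabeling and match the oracle", {
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    pred <- sample(1:3, n, replace = TRUE)
    ref <- sample(1:3, n, replace = TRUE)
    fast <- partition_metrics(pred, ref)
    slow <- pair_count_metrics(pred, ref)
    expect_equal(fast, slow, tolerance = 1e-12)
    # relabeling either side changes nothing
    relab <- c(7, 5, 9)[pred]
    expect_equal(partition_metrics(relab, ref), fast)
    expect_equal(partition_metrics(pred, c(2, 3, 1)[ref]), fast)
  }
})

test_that("the Welch t test matches its closed form and degenerate contract", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0214, tolerance = 1e-2)

  flipped <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(flipped$t, -tt$t)
  expect_equal(flipped$p, tt$p)

  const <- two_sample_t(c(2, 2, 2), c(2, 2))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)
})

test_that("pairwise cluster t tests report a row per cluster pair", {
  set.seed(2)
  X <- matrix(c(rnorm(40, 0), rnorm(40, 10)), ncol = 1)
  fit <- fit_em(X, 2, seed = 1)
  tt <- cluster_t_tests(X, fit$assignment)
  expect_equal(nrow(tt), 1L)
  expect_lt(tt$p, 0.001)
})
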