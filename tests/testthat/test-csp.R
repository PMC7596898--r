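test_that("analytic two-channel case matches the generalized-eigen oracle", {
  # classes with exact second moments diag(4,1) and diag(1,4)
  es <- epochs_with_cov(list(diag(c(4, 1)), diag(c(1, 4))), c(1L, 2L))
  m <- csp(es, n_filters = 2)
  oracle <- geigen_oracle(diag(c(4, 1)) / 5, diag(c(1, 4)) / 5)
  expect_equal(m$eigenvalues, oracle, tolerance = 1e-10)
  expect_equal(m$eigenvalues, c(0.8, 0.2), tolerance = 1e-10)
})

test_that("filters jointly diagonalize both class covariances", {
  rec <- simulate_mi_eeg(n_channels = 6, n_trials_per_class = 25, seed = 6)
  es <- bandpass(segment_epochs(rec))
  m <- csp(es, n_filters = 6)
  D1 <- m$filters %*% m$class_cov[[1]] %*% t(m$filters)
  D2 <- m$filters %*% m$class_cov[[2]] %*% t(m$filters)
  expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-6)
  expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-6)
  # per-filter class variances sum to one (whitened composite)
  expect_equal(diag(D1) + diag(D2), rep(1, 6), tolerance = 1e-8)
  # eigenvalue bookkeeping: lambda = class-1 share, sorted descending
  expect_equal(m$eigenvalues, unname(diag(D1)), tolerance = 1e-8)
  expect_false(is.unsorted(rev(m$eigenvalues)))
  expect_true(all(m$eigenvalues >= 0 & m$eigenvalues <= 1))
})

test_that("CSP refuses single-class input and caps the filter count", {
  es <- epoch_set(array(rnorm(2 * 20 * 4), c(2, 20, 4)), rep(1L, 4), 100)
  expect_error(csp(es), "two classes")
  es2 <- epoch_set(array(rnorm(3 * 50 * 8), c(3, 50, 8)), rep(1:2, 4), 100)
  m <- csp(es2, n_filters = 32)
  expect_equal(m$n_filters, 3L)
  expect_equal(nrow(m$filters), 3L)
  expect_error(csp(es2, n_filters = 5), "even")
})

test_that("features are log normalized variances with unit exp-sum", {
  rec <- simulate_mi_eeg(n_channels = 5, n_trials_per_class = 10, seed = 8)
  es <- bandpass(segment_epochs(rec))
  m <- csp(es, n_filters = 4)
  f <- predict(m, es)
  expect_equal(dim(f), c(20L, 4L))
  expect_equal(rowSums(exp(f)), rep(1, 20), tolerance = 1e-10)
  expect_identical(attr(f, "labels"), es$labels)
  fv <- predict(m, es, type = "var")
  expect_equal(rowSums(fv), rep(1, 20), tolerance = 1e-10)
  expect_equal(exp(f), fv, ignore_attr = TRUE, tolerance = 1e-12)

  zero <- epoch_set(array(0, c(5, 300, 1)), 1L, 100)
  expect_error(predict(m, zero), "degenerate")
})

test_that("common rescaling of all epochs leaves features unchanged", {
  rec <- simulate_mi_eeg(n_channels = 4, n_trials_per_class = 12, seed = 10)
  es <- bandpass(segment_epochs(rec))
  es_scaled <- epoch_set(es$data * 7.3, es$labels, es$fs)
  m1 <- csp(es, n_filters = 4)
  m2 <- csp(es_scaled, n_filters = 4)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(m1$filters / m2$filters), matrix(1, 4, 4), tolerance = 1e-8)
  expect_equal(predict(m1, es), predict(m1, es_scaled), tolerance = 1e-10)
})

test_that("an epoch aligned with one pattern dominates that filter's feature", {
  rec <- simulate_mi_eeg(n_channels = 5, n_trials_per_class = 20, seed = 12)
  es <- bandpass(segment_epochs(rec))
  m <- csp(es, n_filters = 4)
  # rank-1 epoch along the spatial pattern of filter 1
  src_sig <- matrix(sin(2 * pi * 10 * (0:299) / 100), 1L)
  e <- m$patterns[, 1L, drop = FALSE] %*% src_sig +
    1e-6 * matrix(rnorm(5 * 300), 5)   # break exact degeneracy
  f <- predict(m, epoch_set(array(e, c(5, 300, 1)), 1L, 100))
  expect_equal(which.max(f[1L, ]), 1L)
})

test_that("feature matrix at default settings is 280 x 32", {
  set.seed(44)
  es <- epoch_set(array(rnorm(36 * 100 * 280), c(36, 100, 280)),
                  rep(1:2, each = 140), 100)
  m <- csp(es, n_filters = 32)
  expect_equal(m$n_filters, 32L)
  f <- predict(m, es)
  expect_equal(dim(f), c(280L, 32L))
  expect_true(all(is.finite(f)))
})
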