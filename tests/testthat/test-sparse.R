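test_that("dictionary columns are class-grouped and unit-normalized", {
  set.seed(3)
  x <- matrix(rnorm(7 * 4), 7)
  labs <- c(2L, 1L, 2L, 1L, 1L, 2L, 1L)
  d <- src(x, labs)
  expect_equal(d$m, 4L)
  expect_equal(d$N, 7L)
  expect_identical(d$column_classes, c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(colSums(d$A^2), rep(1, 7), tolerance = 1e-12)
  # row_to_column maps each input row to the column holding its feature
  for (i in seq_len(7))
    expect_equal(d$A[, d$row_to_column[i]], x[i, ] / sqrt(sum(x[i, ]^2)),
                 tolerance = 1e-12)
  expect_error(src(x[labs == 1L, ], rep(1L, 4), classes = 1:2),
               "class 2 has no training samples")
})

test_that("training atoms code themselves with zero residual in their class", {
  A <- diag(4)
  d <- src(t(A), c(1L, 1L, 2L, 2L))
  s1 <- sparse_code(d, c(0, 1, 0, 0), epsilon = 0)
  expect_equal(s1$x_hat, c(0, 1, 0, 0))
  expect_equal(s1$residuals, c(0, 1))
  expect_equal(s1$predicted_class, 1L)

  s2 <- sparse_code(d, c(0, 0, 0.6, 0.8), epsilon = 0)
  expect_equal(s2$x_hat, c(0, 0, 0.6, 0.8))
  expect_equal(s2$residuals, c(1, 0))
  expect_equal(s2$predicted_class, 2L)
})

test_that("solver matches the enumeration oracle on 2-sparse instances", {
  set.seed(5)
  for (r in 1:10) {
    inst <- random_bp_instance()
    s <- solve_l1(inst$A, inst$y, epsilon = 1e-8)
    o <- bp_enumeration_oracle(inst$A, inst$y)
    expect_lt(abs(s$l1_norm - o$l1), 1e-4)
    expect_identical(sort(which(abs(s$x) > 1e-4)), o$supp)
    expect_lte(s$fit_residual, 1e-8 + 1e-12)
  }
})

test_that("proximal-gradient route agrees with the homotopy path", {
  set.seed(6)
  for (r in 1:5) {
    inst <- random_bp_instance(m = 5L, N = 10L)
    h <- solve_l1(inst$A, inst$y, epsilon = 0.05, method = "homotopy")
    f <- solve_l1(inst$A, inst$y, epsilon = 0.05, method = "fista")
    # the proximal route is approximate (lambda located by bisection)
    expect_lt(abs(h$l1_norm - f$l1_norm), 1e-2)
  }
})

test_that("coding is positively homogeneous in the input", {
  set.seed(7)
  inst <- random_bp_instance(m = 6L, N = 14L)
  s1 <- solve_l1(inst$A, inst$y, epsilon = 0.02)
  s3 <- solve_l1(inst$A, 3 * inst$y, epsilon = 3 * 0.02)
  expect_equal(s3$x, 3 * s1$x, tolerance = 1e-6)
})

test_that("shrinking epsilon never shrinks the L1 norm", {
  set.seed(8)
  inst <- random_bp_instance(m = 6L, N = 14L)
  eps_grid <- c(0.5, 0.2, 0.05, 0.01, 1e-4)
  l1 <- vapply(eps_grid, function(e) solve_l1(inst$A, inst$y, epsilon = e)$l1_norm,
               numeric(1))
  expect_true(all(diff(l1) >= -1e-9))
})

test_that("class-restricted codes partition the full code", {
  set.seed(9)
  blobs <- make_feature_blobs(8, m = 6, seed = 9)
  d <- src(blobs$x, blobs$labels)
  y <- rnorm(6)
  sc <- sparse_code(d, y)
  parts <- vapply(d$classes, function(k) sc$x_hat * (d$column_classes == k),
                  numeric(d$N))
  expect_equal(rowSums(parts), sc$x_hat, tolerance = 0)
  expect_true(all(sc$residuals >= 0))
  expect_gte(sc$l1_norm, 0)
})

test_that("zero input yields the zero code", {
  d <- src(t(diag(4)), c(1L, 1L, 2L, 2L))
  sc <- sparse_code(d, rep(0, 4), epsilon = 0.01)
  expect_equal(sc$x_hat, rep(0, 4))
  expect_equal(sc$l1_norm, 0)
})

test_that("dimension mismatches are rejected", {
  d <- src(t(diag(4)), c(1L, 1L, 2L, 2L))
  expect_error(sparse_code(d, rep(1, 5)), "dimension")
  expect_error(solve_l1(diag(4), rep(1, 3)), "dimension")
  expect_error(solve_l1(diag(4), rep(1, 4), epsilon = -1), "nonnegative")
})

test_that("SRC classifies training atoms perfectly and handles empty input", {
  blobs <- make_feature_blobs(10, m = 6, seed = 11)
  d <- src(blobs$x, blobs$labels)
  pred <- predict(d, blobs$x, type = "class")
  expect_identical(pred, blobs$labels)
  expect_length(predict(d, blobs$x[0, , drop = FALSE], type = "class"), 0L)
})

test_that("SRC generalizes to held-out draws from separated classes", {
  train <- make_feature_blobs(50, m = 8, seed = 12)
  test <- make_feature_blobs(50, m = 8, seed = 13)
  d <- src(train$x, train$labels)
  pred <- predict(d, test$x, type = "class")
  expect_gte(mean(pred == test$labels), 0.9)
})

test_that("sparse-code matrix has one row per sample, one column per atom", {
  blobs <- make_feature_blobs(10, m = 6, seed = 14)
  d <- src(blobs$x, blobs$labels)
  codes <- sparse_codes(d, blobs$x)
  expect_equal(dim(codes), c(20L, 20L))
  # leave-one-out coding zeroes each sample's own atom
  loo <- sparse_codes(d, blobs$x, leave_one_out = TRUE)
  for (i in 1:20) expect_identical(loo[i, d$row_to_column[i]], 0)
  # self-inclusive coding of an exact atom is the one-hot code
  dI <- src(t(diag(4)), c(1L, 1L, 2L, 2L))
  expect_equal(sparse_codes(dI, t(diag(4)), epsilon = 0)[1, ], c(1, 0, 0, 0))
})
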