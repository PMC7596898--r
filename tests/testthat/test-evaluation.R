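test_that("accuracy follows the percent confusion-count formula", {
  expect_equal(accuracy(list(TP = 49, TN = 50, FP = 1, FN = 0)), 99.0)
  expect_equal(accuracy(list(TP = 0, TN = 0, FP = 50, FN = 50)), 0.0)
  expect_equal(accuracy(list(TP = 50, TN = 50, FP = 0, FN = 0)), 100.0)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "no samples")
})

test_that("accuracy of flipped two-class predictions is complementary", {
  set.seed(2)
  truth <- sample(1:2, 60, replace = TRUE)
  pred <- sample(1:2, 60, replace = TRUE)
  a <- accuracy(confusion_counts(pred, truth))
  b <- accuracy(confusion_counts(3L - pred, truth))
  expect_equal(a + b, 100)
  expect_true(a >= 0 && a <= 100)
})

test_that("cross-entropy matches its closed forms", {
  perfect <- diag(2)[c(1, 2, 1), ]
  expect_identical(cross_entropy(perfect, c(1L, 2L, 1L)), 0)
  expect_equal(cross_entropy(matrix(0.5, 4, 2), c(1L, 2L, 1L, 2L)), log(2),
               tolerance = 1e-12)
  expect_equal(cross_entropy(matrix(c(0.9, 0.1), 1), 1L), -log(0.9),
               tolerance = 1e-12)
  expect_gte(cross_entropy(matrix(c(1e-30, 1 - 1e-30), 1), 1L), 0)
  expect_error(cross_entropy(matrix(0.5, 2, 2), diag(3)), "shape")
})

test_that("shuffle split holds out the last samples of a seeded permutation", {
  sp <- shuffle_split(280, n_test = 100, seed = 42)
  expect_length(sp$train, 180L)
  expect_length(sp$test, 100L)
  expect_setequal(c(sp$train, sp$test), 1:280)
  sp2 <- shuffle_split(280, n_test = 100, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- shuffle_split(280, n_test = 100, seed = 43)
  expect_false(identical(sp$test, sp3$test))
  # the test block is the tail of the shuffled order
  perm <- c(sp$train, sp$test)
  expect_identical(sp$test, perm[181:280])
})

test_that("shuffle split boundary and error cases", {
  sp0 <- shuffle_split(50, n_test = 0, seed = 1)
  expect_length(sp0$test, 0L)
  expect_length(sp0$train, 50L)
  expect_error(shuffle_split(50, n_test = 50, seed = 1), "smaller")
  sp <- shuffle_split(20, n_test = 5, seed = 1, labels = rep(1:2, 10))
  expect_named(sp$class_proportions, c("train", "test"))
})

test_that("the comparison report has the agreed schema", {
  rec <- simulate_mi_eeg(n_channels = 5, n_trials_per_class = 20, seed = 19)
  es <- segment_epochs(rec)
  rep <- compare_pipelines(es, n_filters = 4, n_test = 10, epochs = 5, seed = 19)
  expect_s3_class(rep, "bci_report")
  expect_named(rep, c("src", "fcres", "curves"))
  expect_named(rep$src, c("acc", "loss"))
  expect_named(rep$fcres, c("acc", "loss"))
  expect_true(all(c(rep$src$acc, rep$fcres$acc) >= 0))
  expect_true(all(c(rep$src$acc, rep$fcres$acc) <= 100))
  expect_true(all(c(rep$src$loss, rep$fcres$loss) >= 0))
  expect_equal(nrow(rep$curves), 5L)
})

test_that("seeded evaluation reports are byte-identical", {
  rec <- simulate_mi_eeg(n_channels = 4, n_trials_per_class = 20, seed = 23)
  es <- segment_epochs(rec)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report(compare_pipelines(es, n_filters = 4, n_test = 12, epochs = 4,
                                 seed = 5), f1)
  write_report(compare_pipelines(es, n_filters = 4, n_test = 12, epochs = 4,
                                 seed = 5), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("label-permuted data drives both pipelines to chance", {
  accs <- t(vapply(1:5, function(s) {
    rec <- simulate_mi_eeg(n_channels = 5, n_trials_per_class = 20,
                           class_power_ratio = 8, seed = 100 + s)
    es <- segment_epochs(rec)
    es$labels <- sparsebci:::local_seed(200 + s, sample(es$labels))
    rep <- compare_pipelines(es, n_filters = 4, n_test = 16, epochs = 15,
                             seed = s)
    c(rep$src$acc, rep$fcres$acc)
  }, numeric(2)))
  expect_lt(abs(mean(accs[, 1]) - 50), 15)
  expect_lt(abs(mean(accs[, 2]) - 50), 15)
})
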