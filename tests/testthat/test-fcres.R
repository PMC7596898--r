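test_that("configuration invariants are enforced", {
  expect_error(fcres_config(100, fds_stride = 1), "fds_stride")
  expect_error(fcres_config(100, res_blocks = 0), "res_blocks")
  expect_error(fcres_config(100, dropout_rate = 1), "dropout_rate")
  expect_error(fcres_config(100, n_classes = 1), "n_classes")
  expect_error(fcres_config(3), "fds_kernel")
})

test_that("the layer stack contains the three modules in order", {
  net <- fcres_build(fcres_config(280, seed = 1))
  inv <- layer_inventory(net)
  expect_equal(sum(inv == "residual"), 3L)
  expect_equal(sum(inv == "flatten"), 1L)
  expect_equal(sum(inv == "dense"), 1L)
  # fast down-sampling: exactly one strided conv before the first residual node
  first_res <- which(inv == "residual")[1L]
  expect_equal(sum(inv[seq_len(first_res - 1L)] == "conv"), 1L)
  expect_identical(inv[length(inv)], "dense")
  expect_lt(n_params(net), 1e6)
})

test_that("fast down-sampling length follows stride arithmetic", {
  # stride-s same-padded convolution: output length = ceiling(L / s)
  expect_equal(sparsebci:::conv_out_len(280L, 3L), 94L)
  net <- fcres_build(fcres_config(280, seed = 1))
  x <- array(rnorm(2 * 280), dim = c(2, 280, 1))
  fds <- sparsebci:::seq_forward(net$layers[1], x, training = FALSE)
  expect_equal(dim(fds$out), c(2L, 94L, 16L))
})

test_that("a residual node with silenced branch is the identity map", {
  net <- fcres_build(fcres_config(60, fds_filters = 8, res_filters = c(8, 8, 8),
                                  seed = 2))
  inv <- layer_inventory(net)
  i <- which(inv == "residual")[1L]
  node <- sparsebci:::zero_branch_params(net$layers[[i]])
  expect_length(node$shortcut, 0L)   # equal channels: identity shortcut
  x <- array(rnorm(3 * 20 * 8), dim = c(3, 20, 8))
  out <- sparsebci:::seq_forward(list(node), x, training = FALSE)$out
  expect_identical(out, x)
})

test_that("channel-changing residual nodes use a projection shortcut", {
  net <- fcres_build(fcres_config(60, fds_filters = 8, res_filters = c(16, 16, 16),
                                  seed = 2))
  i <- which(layer_inventory(net) == "residual")[1L]
  sc <- net$layers[[i]]$shortcut
  expect_length(sc, 1L)
  expect_identical(sc[[1L]]$type, "conv")
  expect_equal(sc[[1L]]$kernel, 1L)
})

test_that("untrained network predicts the uniform distribution", {
  net <- fcres_build(fcres_config(40, seed = 3))
  x <- matrix(rnorm(5 * 40), 5)
  pr <- predict(net, x)
  expect_equal(unname(pr$prob), matrix(0.5, 5, 2), tolerance = 1e-12)
  expect_equal(dim(pr$prob), c(5L, 2L))
  expect_equal(rowSums(pr$prob), rep(1, 5), tolerance = 1e-6)
  # ties break to the lowest class index
  expect_identical(pr$class, rep(1L, 5))
})

test_that("initial loss on balanced two-class data is ln 2", {
  net <- fcres_build(fcres_config(40, seed = 4))
  x <- matrix(rnorm(20 * 40), 20)
  pr <- predict(net, x)
  expect_lt(abs(cross_entropy(pr$prob, rep(1:2, 10)) - log(2)), 0.05)
})

test_that("training separates linearly separable blobs", {
  blobs <- make_feature_blobs(100, m = 30, sep = 3, seed = 21)
  fit <- fcres_cnn(blobs$x, blobs$labels, epochs = 150, seed = 21)
  expect_equal(nrow(fit$history), 150L)
  expect_gte(tail(fit$history$train_acc, 1), 0.99)
  expect_true(all(fit$history$train_loss >= 0))
})

test_that("oversized batches degrade to full-batch training without error", {
  blobs <- make_feature_blobs(15, m = 30, seed = 22)
  fit <- fcres_cnn(blobs$x, blobs$labels, epochs = 3, batch_size = 2500,
                   seed = 5)
  expect_equal(fit$trained_epochs, 3L)
})

test_that("zero requested epochs is a no-op", {
  net <- fcres_build(fcres_config(40, seed = 6))
  out <- fcres_train(net, matrix(rnorm(10 * 40), 10), rep(1:2, 5), epochs = 0)
  expect_identical(out, net)
  expect_equal(nrow(out$history), 0L)
})

test_that("training is deterministic given the seed", {
  blobs <- make_feature_blobs(12, m = 30, seed = 23)
  f1 <- fcres_cnn(blobs$x, blobs$labels, epochs = 5, seed = 11)
  f2 <- fcres_cnn(blobs$x, blobs$labels, epochs = 5, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(predict(f1, blobs$x)$prob, predict(f2, blobs$x)$prob)
})

test_that("invalid training inputs are rejected", {
  net <- fcres_build(fcres_config(40, seed = 7))
  x <- matrix(rnorm(10 * 40), 10)
  expect_error(fcres_train(net, x, rep(1L, 10), epochs = 1), "single class")
  expect_error(fcres_train(net, x, rep(1:2, 4), epochs = 1), "labels")
  expect_error(predict(net, matrix(0, 2, 39)), "input_length")
})

test_that("too-short inputs report the minimal feasible length", {
  expect_error(fcres_build(fcres_config(10, seed = 1)), "minimum is")
})
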