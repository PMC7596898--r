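#' Configuration for the fast-compression residual network (FCRes-CNN)
#'
#' The FCRes-CNN classifies a sparse-code vector (length `input_length`,
#' one channel) through three modules: a *fast down-sampling module* -- a
#' convolution with a large stride (default 3) replacing pooling as a
#' learnable compressor, followed by dropout and batch normalization; a
#' stack of *residual convolution modules* -- two serial convolutions (each
#' batch-normalized, ReLU between) whose output is added back to the module
#' input through an identity shortcut (a 1-wide projection convolution when
#' the channel count changes), followed by dropout and max-pooling; and a
#' *classification module* -- a 1-wide convolution reducing the channel
#' dimension, a flatten layer, dropout, and a dense softmax head.
#'
#' @param input_length length of the input code vector (the dictionary
#'   column count N).
#' @param n_classes number of classes k (>= 2).
#' @param fds_stride stride of the fast down-sampling convolution
#'   (default 3).
#' @param fds_filters,fds_kernel filters / kernel width of the fast
#'   down-sampling convolution (defaults 16 / 7).
#' @param res_blocks number of residual modules (default 3).
#' @param res_filters integer vector of per-module filter counts (default
#'   `c(16, 32, 32)`, recycled to `res_blocks`).
#' @param res_kernel kernel width inside residual modules (default 3).
#' @param pool max-pool size after each residual module (default 2).
#' @param cls_filters channels after the classification module's 1-wide
#'   reduction convolution (default 4).
#' @param dropout_rate dropout probability used at every dropout layer
#'   (default 0.3).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size mini-batch size (default 2500; batches larger than the
#'   training set degrade gracefully to full-batch gradient descent).
#' @param epochs default number of training epochs (default 300).
#' @param seed integer seed controlling weight initialization, dropout
#'   masks and shuffling.
#' @return A `fcres_config` list.
#' @export
fcres_config <- function(input_length, n_classes = 2L, fds_stride = 3L,
                         fds_filters = 16L, fds_kernel = 7L, res_blocks = 3L,
                         res_filters = c(16L, 32L, 32L), res_kernel = 3L,
                         pool = 2L, cls_filters = 4L, dropout_rate = 0.3,
                         learning_rate = 0.001, batch_size = 2500L,
                         epochs = 300L, seed = 1L) {
  if (fds_stride < 2L)
    stop_sparsebci("fds_stride must be >= 2 (fast down-sampling)",
                   class = "sparsebci_parameter_error")
  if (res_blocks < 1L)
    stop_sparsebci("res_blocks must be >= 1", class = "sparsebci_parameter_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_sparsebci("dropout_rate must lie in [0, 1)",
                   class = "sparsebci_parameter_error")
  if (n_classes < 2L)
    stop_sparsebci("n_classes must be >= 2", class = "sparsebci_parameter_error")
  if (input_length < fds_kernel)
    stop_sparsebci("input_length must be >= fds_kernel",
                   class = "sparsebci_parameter_error")
  structure(list(input_length = as.integer(input_length),
                 n_classes = as.integer(n_classes),
                 fds_stride = as.integer(fds_stride),
                 fds_filters = as.integer(fds_filters),
                 fds_kernel = as.integer(fds_kernel),
                 res_blocks = as.integer(res_blocks),
                 res_filters = rep_len(as.integer(res_filters), res_blocks),
                 res_kernel = as.integer(res_kernel),
                 pool = as.integer(pool),
                 cls_filters = as.integer(cls_filters),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "fcres_config")
}

# sequence length after the whole stride/pool chain; <1 means infeasible
chain_out_len <- function(cfg, L = cfg$input_length) {
  L <- conv_out_len(L, cfg$fds_stride)
  for (b in seq_len(cfg$res_blocks)) L <- L %/% cfg$pool
  L
}

#' Build an (untrained) FCRes-CNN
#'
#' Instantiates the layer stack described in [fcres_config()]. Convolution
#' and hidden dense weights use He-normal initialization; the softmax head
#' is zero-initialized, so an untrained network predicts the uniform
#' distribution over classes.
#'
#' @param cfg a [fcres_config()].
#' @return An object of class `fcres_cnn` with empty training history.
#' @export
fcres_build <- function(cfg) {
  stopifnot(inherits(cfg, "fcres_config"))
  if (chain_out_len(cfg) < 1L) {
    Lmin <- cfg$fds_kernel
    while (chain_out_len(cfg, Lmin) < 1L) Lmin <- Lmin + 1L
    stop_sparsebci(sprintf(
      "input_length %d too short for the stride/pool chain; minimum is %d",
      cfg$input_length, Lmin), class = "sparsebci_parameter_error")
  }
  local_seed(cfg$seed, {
    layers <- list(
      layer_conv(1L, cfg$fds_filters, cfg$fds_kernel, cfg$fds_stride),
      layer_dropout(cfg$dropout_rate),
      layer_bn(cfg$fds_filters))
    in_ch <- cfg$fds_filters
    for (b in seq_len(cfg$res_blocks)) {
      out_ch <- cfg$res_filters[b]
      branch <- list(layer_conv(in_ch, out_ch, cfg$res_kernel),
                     layer_bn(out_ch),
                     layer_relu(),
                     layer_conv(out_ch, out_ch, cfg$res_kernel),
                     layer_bn(out_ch))
      shortcut <- if (in_ch == out_ch) list()
                  else list(layer_conv(in_ch, out_ch, 1L))
      layers <- c(layers, list(layer_residual(branch, shortcut),
                               layer_dropout(cfg$dropout_rate),
                               layer_maxpool(cfg$pool)))
      in_ch <- out_ch
    }
    flat_dim <- chain_out_len(cfg) * cfg$cls_filters
    layers <- c(layers, list(
      layer_conv(in_ch, cfg$cls_filters, 1L),
      layer_flatten(),
      layer_dropout(cfg$dropout_rate),
      layer_dense(flat_dim, cfg$n_classes, init = "zero")))
    structure(list(config = cfg, layers = layers,
                   history = empty_history(), trained_epochs = 0L,
                   classes = seq_len(cfg$n_classes)),
              class = "fcres_cnn")
  })
}

empty_history <- function() {
  data.frame(epoch = integer(0), train_loss = numeric(0),
             train_acc = numeric(0), val_loss = numeric(0),
             val_acc = numeric(0))
}

#' Layer inventory of a network
#'
#' @param net a `fcres_cnn`.
#' @return Character vector of layer type names in forward order; residual
#'   nodes appear as `"residual"`.
#' @export
layer_inventory <- function(net) {
  stopifnot(inherits(net, "fcres_cnn"))
  vapply(net$layers, `[[`, character(1), "type")
}

#' Number of trainable parameters
#' @param net a `fcres_cnn`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) as.integer(count_params(net$layers))

codes_to_tensor <- function(x, input_length) {
  x <- as.matrix(x)
  if (ncol(x) != input_length)
    stop_sparsebci("code length ", ncol(x), " does not match input_length ",
                   input_length, class = "sparsebci_validation_error")
  array(x, dim = c(nrow(x), ncol(x), 1L))
}

#' Train an FCRes-CNN on sparse codes
#'
#' Minimizes the categorical cross-entropy by mini-batch Adam. When
#' `batch_size` exceeds the number of training samples the whole set forms a
#' single batch per epoch. The per-epoch history records loss and accuracy
#' on the training data (and on a held-out validation fraction, if
#' requested), both evaluated in inference mode. Fully reproducible given
#' the configuration seed.
#'
#' @param net a `fcres_cnn` from [fcres_build()].
#' @param codes numeric matrix, samples x input_length (the sparse-code
#'   matrix).
#' @param labels integer class labels in `1..n_classes`.
#' @param epochs number of epochs; defaults to the configuration value. 0
#'   returns the network unchanged.
#' @param val_fraction fraction of samples held out for validation
#'   monitoring (default 0).
#' @param verbose print a line every 25 epochs.
#' @return The trained `fcres_cnn` with filled `history`.
#' @export
fcres_train <- function(net, codes, labels, epochs = NULL, val_fraction = 0,
                        verbose = FALSE) {
  stopifnot(inherits(net, "fcres_cnn"))
  cfg <- net$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (epochs == 0L) return(net)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_sparsebci("training labels contain a single class",
                   class = "sparsebci_parameter_error")
  if (any(labels < 1L | labels > cfg$n_classes))
    stop_sparsebci("labels must lie in 1..n_classes",
                   class = "sparsebci_parameter_error")
  x <- codes_to_tensor(codes, cfg$input_length)
  n <- dim(x)[1L]
  if (n != length(labels))
    stop_sparsebci("rows of codes must match length of labels",
                   class = "sparsebci_validation_error")

  local_seed(cfg$seed + 1L, {
    idx_val <- integer(0)
    if (val_fraction > 0) {
      n_val <- max(1L, round(val_fraction * n))
      idx_val <- sample(n, n_val)
    }
    idx_tr <- setdiff(seq_len(n), idx_val)
    xtr <- x[idx_tr, , , drop = FALSE]; ytr <- labels[idx_tr]
    xva <- x[idx_val, , , drop = FALSE]; yva <- labels[idx_val]
    bs <- min(cfg$batch_size, length(idx_tr))
    onehot <- diag(cfg$n_classes)

    layers <- net$layers
    adam <- adam_init(layers)
    t_step <- 0L
    hist <- vector("list", epochs)

    eval_set <- function(layers, xs, ys) {
      if (!length(ys)) return(c(NA_real_, NA_real_))
      fw <- seq_forward(layers, xs, training = FALSE)
      p <- softmax_rows(fw$out)
      loss <- -mean(log(pmax(p[cbind(seq_along(ys), ys)], 1e-12)))
      acc <- mean(apply(p, 1L, which.max) == ys)
      c(loss, acc)
    }

    for (ep in seq_len(epochs)) {
      perm <- sample(length(ytr))
      for (start in seq(1L, length(ytr), by = bs)) {
        take <- perm[start:min(start + bs - 1L, length(ytr))]
        xb <- xtr[take, , , drop = FALSE]
        yb <- ytr[take]
        fw <- seq_forward(layers, xb, training = TRUE)
        layers <- seq_update_state(layers, fw$states)
        p <- softmax_rows(fw$out)
        loss <- -mean(log(pmax(p[cbind(seq_along(yb), yb)], 1e-12)))
        if (!is.finite(loss))
          stop_sparsebci("training diverged: non-finite loss at epoch ", ep,
                         class = "sparsebci_training_error")
        dlogits <- (p - onehot[yb, , drop = FALSE]) / length(yb)
        bw <- seq_backward(layers, fw$caches, dlogits)
        t_step <- t_step + 1L
        upd <- adam_apply(layers, bw$grads, adam, cfg$learning_rate, t_step)
        layers <- upd$layers; adam <- upd$state
      }
      tr <- eval_set(layers, xtr, ytr)
      va <- eval_set(layers, xva, yva)
      hist[[ep]] <- c(tr, va)
      if (verbose && ep %% 25L == 0L)
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep, tr[1L], tr[2L]))
    }
    hm <- do.call(rbind, hist)
    net$layers <- layers
    net$history <- rbind(net$history,
                         data.frame(epoch = net$trained_epochs + seq_len(epochs),
                                    train_loss = hm[, 1L], train_acc = hm[, 2L],
                                    val_loss = hm[, 3L], val_acc = hm[, 4L]))
    net$trained_epochs <- net$trained_epochs + as.integer(epochs)
    net
  })
}

#' Fit an FCRes-CNN classifier to sparse codes
#'
#' Convenience wrapper: builds the network for the given code width and
#' class count, then trains it. See [fcres_config()] for tunables.
#'
#' @param codes samples x N sparse-code matrix.
#' @param labels integer class labels.
#' @param ... passed to [fcres_config()] (e.g. `epochs`, `seed`).
#' @param val_fraction validation fraction for the history curves.
#' @return A trained `fcres_cnn`.
#' @examples
#' \donttest{
#' codes <- rbind(matrix(rnorm(200, 1), 20), matrix(rnorm(200, -1), 20))
#' fit <- fcres_cnn(codes, rep(1:2, each = 20), epochs = 30, seed = 3)
#' predict(fit, codes)$class
#' }
#' @export
fcres_cnn <- function(codes, labels, ..., val_fraction = 0) {
  labels <- as.integer(labels)
  cfg <- fcres_config(input_length = ncol(as.matrix(codes)),
                      n_classes = max(2L, length(unique(labels))), ...)
  net <- fcres_build(cfg)
  fcres_train(net, codes, labels, val_fraction = val_fraction)
}

#' Predict classes or probabilities from a fitted FCRes-CNN
#'
#' @param object a `fcres_cnn`.
#' @param codes samples x input_length code matrix.
#' @param ... unused.
#' @return List with `prob` (rows sum to 1) and `class` (argmax labels,
#'   ties to the lowest index).
#' @export
predict.fcres_cnn <- function(object, codes, ...) {
  x <- codes_to_tensor(codes, object$config$input_length)
  fw <- seq_forward(object$layers, x, training = FALSE)
  p <- softmax_rows(fw$out)
  colnames(p) <- object$classes
  list(prob = p, class = object$classes[apply(p, 1L, which.max)])
}

#' @export
print.fcres_cnn <- function(x, ...) {
  cat(sprintf("<fcres_cnn> input %d, %d classes, %d parameters, trained %d epochs\n",
              x$config$input_length, x$config$n_classes, n_params(x),
              x$trained_epochs))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, accuracy %.3f\n",
                last$train_loss, last$train_acc))
  }
  invisible(x)
}

#' Plot FCRes-CNN training curves
#' @param x a trained `fcres_cnn`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fcres_cnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", ylim = c(0, 1), ...)
  if (any(is.finite(h$val_acc))) graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ...)
  if (any(is.finite(h$val_loss))) graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}
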