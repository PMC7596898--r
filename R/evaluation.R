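#' Confusion counts for a two-class prediction
#'
#' Class 1 is treated as the positive class: `TP` = truth 1 predicted 1,
#' `TN` = truth 2 predicted 2, `FP` = truth 2 predicted 1, `FN` = truth 1
#' predicted 2.
#'
#' @param predicted,truth integer vectors of class labels in `{1, 2}`.
#' @return List with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  list(TP = sum(predicted == 1L & truth == 1L),
       TN = sum(predicted == 2L & truth == 2L),
       FP = sum(predicted == 1L & truth == 2L),
       FN = sum(predicted == 2L & truth == 1L))
}

#' Classification accuracy in percent
#'
#' `Accuracy(%) = 100 (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts a list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return Accuracy percentage in `[0, 100]`.
#' @examples
#' accuracy(list(TP = 49, TN = 50, FP = 1, FN = 0))
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (tot == 0) stop_sparsebci("no samples", class = "sparsebci_parameter_error")
  100 * (counts$TP + counts$TN) / tot
}

#' Categorical cross-entropy loss
#'
#' `-(1/n) sum_i sum_j y_ij ln(yhat_ij)` with predicted probabilities
#' clipped to `[1e-12, 1]` before the logarithm.
#'
#' @param y_hat n x m matrix of predicted class probabilities.
#' @param y_true n x m one-hot truth matrix, or an integer label vector
#'   which is one-hot encoded against the columns of `y_hat`.
#' @return Nonnegative loss.
#' @examples
#' cross_entropy(matrix(0.5, 2, 2), c(1L, 2L))  # ln 2
#' @export
cross_entropy <- function(y_hat, y_true) {
  y_hat <- as.matrix(y_hat)
  if (is.null(dim(y_true))) {
    lab <- as.integer(y_true)
    y_true <- matrix(0, length(lab), ncol(y_hat))
    y_true[cbind(seq_along(lab), lab)] <- 1
  }
  if (!all(dim(y_hat) == dim(y_true)))
    stop_sparsebci("shape mismatch between predictions and truths",
                   class = "sparsebci_validation_error")
  -mean(rowSums(y_true * log(pmin(pmax(y_hat, 1e-12), 1))))
}

#' Shuffle-then-hold-out split
#'
#' Randomly permutes the sample indices under the given seed and holds out
#' the last `n_test` shuffled samples as the test set -- the random-shuffle /
#' fixed-tail protocol conventional for small motor-imagery datasets (280
#' trials, last 100 as test). Class proportions are reported but not
#' enforced.
#'
#' @param n number of samples (or a vector/matrix whose rows are counted).
#' @param n_test test-set size (< n).
#' @param seed integer seed; identical seeds give identical partitions.
#' @return List with integer index vectors `train` and `test` and
#'   `class_proportions` (NULL unless `labels` is supplied).
#' @param labels optional labels used only to report class proportions.
#' @export
shuffle_split <- function(n, n_test = 100L, seed = 1L, labels = NULL) {
  if (is.matrix(n)) n <- nrow(n) else if (length(n) > 1L) n <- length(n)
  n <- as.integer(n); n_test <- as.integer(n_test)
  if (n_test >= n)
    stop_sparsebci("n_test must be smaller than the number of samples",
                   class = "sparsebci_parameter_error")
  perm <- local_seed(seed, sample(n))
  test <- if (n_test > 0L) perm[(n - n_test + 1L):n] else integer(0)
  train <- perm[seq_len(n - n_test)]
  props <- NULL
  if (!is.null(labels))
    props <- list(train = prop.table(table(labels[train])),
                  test = if (n_test) prop.table(table(labels[test])) else NULL)
  list(train = train, test = test, class_proportions = props)
}

#' Run and compare the SRC baseline and the SRC + FCRes-CNN pipeline
#'
#' Executes the full two-class pipeline on a labeled epoch set: band-pass
#' filtering (unless disabled), shuffle/hold-out split, CSP fitting on the
#' training epochs, feature extraction, dictionary construction, then (a)
#' minimum-residual SRC classification of the test features and (b)
#' FCRes-CNN classification of the sparse codes (training codes computed
#' leave-one-column-out by default, so no training sample is represented by
#' its own atom). Accuracies use the percent confusion-count formula; losses
#' are categorical cross-entropy, with SRC residuals mapped to softmin
#' pseudo-probabilities so the same loss applies to both pipelines.
#'
#' @param es a labeled two-class `epoch_set`.
#' @param n_filters CSP filter count (default 32, capped at the channel
#'   count).
#' @param band band-pass edges in Hz, or NULL to skip filtering (e.g. when
#'   `es` is already filtered).
#' @param n_test held-out test-set size (default 100).
#' @param epsilon sparse-coding slack (fraction of `||y||`, default 0.01).
#' @param epochs FCRes-CNN training epochs (default 150).
#' @param seed integer seed driving the split and the network.
#' @param leave_one_out compute training codes leave-one-column-out
#'   (default TRUE).
#' @param val_fraction validation fraction for the network curves
#'   (default 0, i.e. all training samples are used for fitting).
#' @param ... further arguments to [fcres_config()].
#' @return An object of class `bci_report`: list with `src` (`acc`, `loss`),
#'   `fcres` (`acc`, `loss`) and `curves` (per-epoch network history).
#' @export
compare_pipelines <- function(es, n_filters = 32L, band = c(8, 15),
                              n_test = 100L, epsilon = 0.01, epochs = 150L,
                              seed = 1L, leave_one_out = TRUE,
                              val_fraction = 0, ...) {
  stopifnot(inherits(es, "epoch_set"))
  if (!is.null(band)) es <- bandpass(es, band[1L], band[2L])
  sp <- shuffle_split(length(es), n_test = n_test, seed = seed,
                      labels = es$labels)
  es_tr <- es[sp$train]; es_te <- es[sp$test]

  model <- csp(es_tr, n_filters = n_filters)
  f_tr <- predict(model, es_tr)
  f_te <- predict(model, es_te)

  d <- src(f_tr, es_tr$labels)
  src_resid <- predict(d, f_te, type = "residuals", epsilon = epsilon)
  src_pred <- d$classes[apply(src_resid, 1L, which.min)]
  src_prob <- exp(-src_resid) / rowSums(exp(-src_resid))
  src_acc <- accuracy(confusion_counts(src_pred, es_te$labels))
  src_loss <- cross_entropy(src_prob, es_te$labels)

  codes_tr <- sparse_codes(d, f_tr, epsilon = epsilon,
                           leave_one_out = leave_one_out)
  codes_te <- sparse_codes(d, f_te, epsilon = epsilon)
  net <- fcres_cnn(codes_tr, es_tr$labels, epochs = epochs, seed = seed,
                   val_fraction = val_fraction, ...)
  pr <- predict(net, codes_te)
  fc_acc <- accuracy(confusion_counts(pr$class, es_te$labels))
  fc_loss <- cross_entropy(pr$prob, es_te$labels)

  structure(list(src = list(acc = src_acc, loss = src_loss),
                 fcres = list(acc = fc_acc, loss = fc_loss),
                 curves = net$history),
            class = "bci_report")
}

#' @export
print.bci_report <- function(x, ...) {
  cat("<bci_report>\n")
  cat(sprintf("  SRC baseline:      accuracy %6.2f%%  loss %.4f\n",
              x$src$acc, x$src$loss))
  cat(sprintf("  SRC + FCRes-CNN:   accuracy %6.2f%%  loss %.4f\n",
              x$fcres$acc, x$fcres$loss))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the report deterministically (fixed field order, full precision)
#' so that identical seeded runs produce byte-identical files.
#'
#' @param report a `bci_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bci_report"))
  jsonlite::write_json(list(src = report$src, fcres = report$fcres,
                            curves = report$curves),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
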