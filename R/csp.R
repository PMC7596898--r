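#' Fit common spatial patterns (CSP) filters on a two-class epoch set
#'
#' CSP finds spatial filters (linear channel combinations) that maximise the
#' variance of one class while minimising the other, by jointly
#' diagonalizing the two class-average covariance matrices. Per-trial
#' covariances are trace-normalized (`C = X X' / tr(X X')`) before averaging,
#' which equalizes trial power and is the standard CSP recipe. The composite
#' covariance is whitened; a rotation then diagonalizes the whitened class-1
#' covariance, giving filters whose class-1 eigenvalues `lambda_j` lie in
#' `[0, 1]` with `lambda(class1) + lambda(class2) = 1` per filter. The
#' `n_filters/2` filters with largest and smallest `lambda` (the most
#' discriminative ends of the spectrum) are retained.
#'
#' @param es an `epoch_set` containing epochs of exactly two classes.
#' @param n_filters even number of filters to keep (default 32). When the
#'   channel count is smaller, all available filters are used and the actual
#'   count is recorded.
#' @param shrinkage shrinkage weight `gamma` applied as
#'   `C <- (1 - gamma) C + gamma (tr(C)/channels) I` when the composite
#'   covariance is near-singular. Default `1e-6`.
#' @return An object of class `csp`: list with `filters` (n_filters x
#'   channels, rows are spatial filters, eigenvalues sorted descending),
#'   `eigenvalues` (class-1 variance ratios of the kept filters),
#'   `patterns` (channels x n_filters spatial patterns, columns of the
#'   inverse full filter matrix), `n_filters`, `fitted_channels`, and the
#'   averaged class covariances used in fitting.
#' @examples
#' es <- bandpass(segment_epochs(simulate_mi_eeg(n_trials_per_class = 20, seed = 7)))
#' m <- csp(es, n_filters = 6)
#' m
#' @export
csp <- function(es, n_filters = 32L, shrinkage = 1e-6) {
  stopifnot(inherits(es, "epoch_set"))
  classes <- sort(unique(es$labels))
  if (length(classes) != 2L)
    stop_sparsebci("CSP requires two classes", class = "sparsebci_parameter_error")
  n_filters <- as.integer(n_filters)
  if (n_filters < 2L || n_filters %% 2L != 0L)
    stop_sparsebci("`n_filters` must be a positive even integer",
                   class = "sparsebci_parameter_error")
  ch <- dim(es$data)[1L]

  class_cov <- function(lbl) {
    idx <- which(es$labels == lbl)
    C <- matrix(0, ch, ch)
    for (i in idx) {
      X <- es$data[, , i]
      S <- tcrossprod(X)
      tr <- sum(diag(S))
      if (tr <= 0)
        stop_sparsebci("degenerate (zero-variance) epoch at index ", i,
                       class = "sparsebci_validation_error")
      C <- C + S / tr
    }
    C / length(idx)
  }
  C1 <- class_cov(classes[1L])
  C2 <- class_cov(classes[2L])

  Cc <- C1 + C2
  ev <- eigen(Cc, symmetric = TRUE)
  if (min(ev$values) < max(ev$values) * 1e-10) {
    warning("near-singular composite covariance; applying shrinkage regularization")
    reg <- function(C) (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / ch) * diag(ch)
    C1 <- reg(C1); C2 <- reg(C2)
    ev <- eigen(C1 + C2, symmetric = TRUE)
  }
  # whitening of the composite covariance, then rotation diagonalizing C1
  P <- diag(1 / sqrt(ev$values), ch) %*% t(ev$vectors)
  S1 <- P %*% C1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  rot <- eigen(S1, symmetric = TRUE)       # values descending
  W_full <- t(rot$vectors) %*% P           # rows = filters, lambda descending
  A_full <- solve(W_full)                  # columns = spatial patterns

  # deterministic sign: largest-magnitude filter coefficient positive
  for (j in seq_len(ch)) {
    s <- sign(W_full[j, which.max(abs(W_full[j, ]))])
    W_full[j, ] <- s * W_full[j, ]
    A_full[, j] <- s * A_full[, j]
  }

  n_eff <- min(n_filters, ch)
  sel <- if (n_eff == ch) seq_len(ch) else
    c(seq_len(n_eff %/% 2L), (ch - n_eff %/% 2L + 1L):ch)

  structure(list(filters = W_full[sel, , drop = FALSE],
                 eigenvalues = pmin(pmax(rot$values[sel], 0), 1),
                 patterns = A_full[, sel, drop = FALSE],
                 n_filters = n_eff,
                 fitted_channels = ch,
                 classes = classes,
                 class_cov = list(C1, C2)),
            class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %d filters on %d channels; class-%d eigenvalue range [%.3f, %.3f]\n",
              x$n_filters, x$fitted_channels, x$classes[1L],
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' @export
coef.csp <- function(object, ...) object$filters

#' Extract CSP band-power features from epochs
#'
#' Projects each epoch through the fitted spatial filters and summarizes
#' each projection by its variance share. With `type = "logvar"` (default)
#' feature `j` is `log(var_j / sum_k var_k)`, the log of the normalized
#' variance; `type = "var"` returns the normalized variances themselves.
#'
#' @param object a fitted [csp()] model.
#' @param es an `epoch_set` with the same channel count the model was
#'   fitted on (a single channels x T matrix is also accepted).
#' @param type feature functional, `"logvar"` or `"var"`.
#' @param ... unused.
#' @return Numeric matrix, n_epochs x n_filters, with the epoch labels (if
#'   any) in attribute `labels`.
#' @export
predict.csp <- function(object, es, type = c("logvar", "var"), ...) {
  type <- match.arg(type)
  if (is.matrix(es)) es <- epoch_set(array(es, dim = c(dim(es), 1L)), NA_integer_, 1)
  stopifnot(inherits(es, "epoch_set"))
  if (dim(es$data)[1L] != object$fitted_channels)
    stop_sparsebci("epoch channel count does not match the fitted model",
                   class = "sparsebci_validation_error")
  n <- dim(es$data)[3L]
  out <- matrix(NA_real_, n, object$n_filters)
  for (i in seq_len(n)) {
    Z <- object$filters %*% es$data[, , i]
    v <- apply(Z, 1L, stats::var)
    tot <- sum(v)
    if (!is.finite(tot) || tot <= 0)
      stop_sparsebci("degenerate epoch (zero variance) at index ", i,
                     class = "sparsebci_validation_error")
    out[i, ] <- if (type == "logvar") log(v / tot) else v / tot
  }
  attr(out, "labels") <- es$labels
  out
}

#' @rdname predict.csp
#' @export
csp_features <- function(object, es, type = c("logvar", "var"))
  predict(object, es, type = match.arg(type))
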