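#' Build a sparse-representation classifier (redundant dictionary) from
#' training features
#'
#' Stacks the training feature vectors as columns of a dictionary matrix
#' `A`, grouped by class in ascending class order and unit-L2-normalized.
#' A test feature is then represented as a sparse linear combination of
#' dictionary columns (found by L1-norm minimization, see [solve_l1()]) and
#' assigned to the class whose columns reconstruct it with the smallest
#' residual.
#'
#' In the intended regime the feature dimension `m` is smaller than the
#' number of training columns `N`, so the linear system is underdetermined
#' and the L1 penalty selects a sparse representation.
#'
#' @param x numeric matrix of training features, one row per sample
#'   (n x m).
#' @param labels integer class labels, one per row; every class must own at
#'   least one sample.
#' @param classes integer vector of the class ids the dictionary must
#'   cover; defaults to the classes present in `labels`. A listed class
#'   with no training samples is an error.
#' @return An object of class `src`: list with `A` (m x N dictionary,
#'   unit-norm columns), `column_classes`, `classes`, `m`, `N`, and
#'   `row_to_column` mapping input rows to dictionary columns.
#' @examples
#' x <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
#' d <- src(x, rep(1:2, each = 10))
#' d
#' @export
src <- function(x, labels, classes = sort(unique(labels))) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- sort(as.integer(classes))
  for (k in classes)
    if (!any(labels == k))
      stop_sparsebci("class ", k, " has no training samples",
                     class = "sparsebci_parameter_error")
  ord <- order(labels)
  A <- t(x[ord, , drop = FALSE])
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0))
    stop_sparsebci("zero-norm training feature at row ",
                   ord[which(nrm == 0)[1L]], class = "sparsebci_validation_error")
  A <- sweep(A, 2L, nrm, "/")
  structure(list(A = A, column_classes = labels[ord], classes = classes,
                 m = nrow(A), N = ncol(A),
                 row_to_column = order(ord)),
            class = "src")
}

#' @export
print.src <- function(x, ...) {
  cat(sprintf("<src> dictionary %d x %d (%s)\n", x$m, x$N,
              paste(sprintf("class %d: %d cols", x$classes,
                            tabulate(factor(x$column_classes, x$classes))),
                    collapse = ", ")))
  invisible(x)
}

# one FISTA run for 0.5||Ax - y||^2 + lambda ||x||_1, warm-started at x0
fista_lasso <- function(A, y, lambda, x0, L, max_iter, tol) {
  x <- x0; z <- x0; t_k <- 1
  Aty <- crossprod(A, y)
  AtA <- crossprod(A)
  for (it in seq_len(max_iter)) {
    grad <- AtA %*% z - Aty
    x_new <- z - grad / L
    x_new <- sign(x_new) * pmax(abs(x_new) - lambda / L, 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + ((t_k - 1) / t_new) * (x_new - x)
    delta <- max(abs(x_new - x))
    x <- x_new; t_k <- t_new
    if (delta < tol) return(list(x = as.numeric(x), iterations = it, converged = TRUE))
  }
  list(x = as.numeric(x), iterations = max_iter, converged = FALSE)
}

# Exact L1-regularization path (LARS-style homotopy with the lasso
# modification), walked from lambda_max down until ||A x - y||_2 <= epsilon.
# Within a path segment the active-set solution is linear in lambda and the
# active-set least-squares residual r0 is orthogonal to the active columns,
# so ||r(lambda)||^2 = ||r0||^2 + lambda^2 ||u||^2 and the constraint
# boundary can be hit exactly. Returns NULL on a degenerate active set so
# the caller can fall back to the proximal-gradient route.
bp_homotopy <- function(A, y, epsilon, max_steps) {
  N <- ncol(A)
  x <- numeric(N)
  c_all <- drop(crossprod(A, y))
  lam <- max(abs(c_all))
  act <- which.max(abs(c_all))
  s <- sign(c_all[act])
  tolr <- 1e-12 * max(1, lam)
  for (step in seq_len(max_steps)) {
    Aa <- A[, act, drop = FALSE]
    G <- crossprod(Aa)
    sol <- tryCatch(list(gs = solve(G, s), gy = solve(G, crossprod(Aa, y))),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    u <- drop(Aa %*% sol$gs)          # d r / d lambda
    r0 <- y - drop(Aa %*% sol$gy)     # residual at lambda -> 0
    rr0 <- sum(r0^2); uu <- sum(u^2)
    x_at <- function(l) {
      xx <- numeric(N); xx[act] <- drop(sol$gy) - l * drop(sol$gs); xx
    }
    lam_eps <- if (sqrt(rr0) <= epsilon + 1e-10 && uu > 0)
      sqrt(max(epsilon^2 - rr0, 0) / uu) else NA_real_

    # leave events: active coefficient crosses zero
    l_leave <- drop(sol$gy) / drop(sol$gs)
    l_leave[!is.finite(l_leave) | l_leave <= tolr | l_leave >= lam - tolr] <- 0
    # join events: inactive correlation catches up with lambda
    inact <- setdiff(seq_len(N), act)
    l_join <- numeric(0); j_idx <- integer(0); j_sign <- numeric(0)
    if (length(inact)) {
      a_r0 <- drop(crossprod(A[, inact, drop = FALSE], r0))
      a_u <- drop(crossprod(A[, inact, drop = FALSE], u))
      for (sgn in c(1, -1)) {
        cand <- a_r0 / (sgn - a_u)
        ok <- is.finite(cand) & cand > tolr & cand < lam - tolr
        l_join <- c(l_join, cand[ok])
        j_idx <- c(j_idx, inact[ok])
        j_sign <- c(j_sign, rep(sgn, sum(ok)))
      }
    }
    lam_next <- max(c(l_leave, l_join, 0))
    if (!is.na(lam_eps) && lam_eps >= lam_next - tolr && lam_eps <= lam + tolr)
      return(list(x = x_at(max(lam_eps, 0)), steps = step))
    if (lam_next <= tolr) {
      # path exhausted: lambda -> 0 least-squares point on the active set
      return(list(x = x_at(0), steps = step))
    }
    if (length(l_join) && max(l_join) >= lam_next - tolr) {
      pick <- which.max(l_join)
      act <- c(act, j_idx[pick])
      s <- c(s, j_sign[pick])
    } else {
      drop_j <- which.max(l_leave)
      act <- act[-drop_j]
      s <- s[-drop_j]
      if (!length(act)) return(list(x = numeric(N), steps = step))
    }
    lam <- lam_next
  }
  NULL
}

#' Sparse coding by L1-norm minimization (basis pursuit denoising)
#'
#' Solves `min ||x||_1 subject to ||A x - y||_2 <= epsilon`, the
#' noise-relaxed basis-pursuit problem. The default `"homotopy"` method
#' walks the exact L1-regularization path (LARS with the lasso
#' modification) from `lambda_max` down to the lambda at which the
#' constraint is met at its boundary; it is exact up to floating point and
#' fast in the dictionary regime used here. The `"fista"` method is
#' proximal-gradient descent (iterative shrinkage with momentum) on the
#' Lagrangian, with the multiplier located by continuation plus bisection.
#' Either way, a least-squares polish over candidate supports (smallest
#' support first) then tightens the solution; a polished point is accepted
#' only when it is feasible and improves the L1 objective, so the returned
#' value is the best feasible point found.
#'
#' @param A dictionary matrix (m x N) or an [src()] object.
#' @param y length-m numeric vector to be coded.
#' @param epsilon nonnegative reconstruction slack (absolute, same scale as
#'   `y`).
#' @param max_iter iteration budget: path segments for `"homotopy"`, FISTA
#'   iterations per lambda for `"fista"` (default 5000).
#' @param tol convergence tolerance on the iterate change (`"fista"` only,
#'   default 1e-8).
#' @param method `"homotopy"` (exact path, default) or `"fista"`.
#' @return List with `x` (length-N coefficients), `l1_norm`, `fit_residual`
#'   (`||A x - y||_2`), `converged`, `iterations`.
#' @examples
#' A <- diag(4)
#' solve_l1(A, c(0, 1, 0, 0), epsilon = 0)$x
#' @export
solve_l1 <- function(A, y, epsilon = 0.01 * sqrt(sum(y^2)), max_iter = 5000L,
                     tol = 1e-8, method = c("homotopy", "fista")) {
  method <- match.arg(method)
  if (inherits(A, "src")) A <- A$A
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (nrow(A) != length(y))
    stop_sparsebci("dimension mismatch: dictionary has m = ", nrow(A),
                   " but y has length ", length(y),
                   class = "sparsebci_validation_error")
  if (epsilon < 0)
    stop_sparsebci("epsilon must be nonnegative", class = "sparsebci_parameter_error")
  N <- ncol(A)
  ynorm <- sqrt(sum(y^2))
  if (ynorm <= epsilon || ynorm == 0)
    return(list(x = numeric(N), l1_norm = 0, fit_residual = ynorm,
                converged = TRUE, iterations = 0L))

  resid_of <- function(x) sqrt(sum((A %*% x - y)^2))
  x <- NULL; conv <- TRUE; iters <- 0L
  if (method == "homotopy") {
    hom <- bp_homotopy(A, y, epsilon, max_steps = max(10L * min(dim(A)), 200L))
    if (!is.null(hom)) { x <- hom$x; iters <- hom$steps }
  }
  if (is.null(x)) {
    # proximal-gradient route: continuation in lambda, then bisection
    # toward the largest lambda whose residual still meets epsilon
    L <- (svd(A, nu = 0, nv = 0)$d[1L])^2
    lam_max <- max(abs(crossprod(A, y)))
    lam_hi <- lam_max; lam_lo <- NULL
    x <- numeric(N)
    lam <- lam_max / 2
    repeat {
      fit <- fista_lasso(A, y, lam, x, L, max_iter, tol)
      x <- fit$x; conv <- conv && fit$converged; iters <- iters + fit$iterations
      if (resid_of(x) <= epsilon) { lam_lo <- lam; break }
      lam_hi <- lam
      lam <- lam / 4
      if (lam < lam_max * 1e-12) { lam_lo <- lam; break }
    }
    if (!is.null(lam_lo) && epsilon > 0) {
      x_feas <- if (resid_of(x) <= epsilon) x else NULL
      for (b in seq_len(12L)) {
        lam <- sqrt(lam_lo * lam_hi)
        fit <- fista_lasso(A, y, lam, x, L, max_iter, tol)
        iters <- iters + fit$iterations
        if (resid_of(fit$x) <= epsilon) { lam_lo <- lam; x_feas <- fit$x }
        else lam_hi <- lam
        x <- fit$x
        if (lam_hi / lam_lo < 1.05) break
      }
      if (!is.null(x_feas)) x <- x_feas
    }
  }
  # support polish: smallest least-squares support that stays feasible
  best <- list(x = x,
               l1 = if (resid_of(x) <= epsilon + 1e-12) sum(abs(x)) else Inf)
  ordidx <- order(abs(x), decreasing = TRUE)
  ordidx <- ordidx[abs(x[ordidx]) > max(tol, 1e-10 * max(abs(x)))]
  smax <- min(length(ordidx), nrow(A))
  for (s in seq_len(smax)) {
    S <- ordidx[seq_len(s)]
    xs <- numeric(N)
    fitls <- tryCatch(qr.solve(A[, S, drop = FALSE], y), error = function(e) NULL)
    if (is.null(fitls)) next
    xs[S] <- fitls
    if (resid_of(xs) <= epsilon + 1e-12 && sum(abs(xs)) <= best$l1 + 1e-12)
      best <- list(x = xs, l1 = sum(abs(xs)))
  }
  x <- best$x
  final_resid <- resid_of(x)
  if (final_resid > epsilon + 1e-9 * max(1, ynorm)) {
    conv <- FALSE
    warning("solve_l1 did not meet the epsilon constraint within max_iter")
  }
  list(x = x, l1_norm = sum(abs(x)), fit_residual = final_resid,
       converged = conv, iterations = iters)
}

# per-class residuals r_i(y) = ||y - A delta_i(x)||_2
class_residuals <- function(d, y, x) {
  vapply(d$classes, function(k) {
    xk <- x * (d$column_classes == k)
    sqrt(sum((y - d$A %*% xk)^2))
  }, numeric(1))
}

#' Sparse-code one feature vector against a dictionary
#'
#' Runs [solve_l1()] for a single (L2-normalized) feature vector and
#' derives the per-class residuals and the minimum-residual class decision.
#'
#' @param d an [src()] dictionary.
#' @param y length-m feature vector.
#' @param epsilon reconstruction slack as a fraction of `||y||_2`
#'   (default 0.01).
#' @param max_iter,tol passed to [solve_l1()].
#' @param exclude_column optional dictionary column index to drop before
#'   coding (leave-one-out coding for training samples; the returned code
#'   keeps length N with a zero at the excluded position).
#' @return A `sparse_code` object: list with `x_hat`, `residuals` (one per
#'   class), `predicted_class` (argmin residual, ties to the lowest class
#'   index), `l1_norm`, `fit_residual`, `converged`.
#' @export
sparse_code <- function(d, y, epsilon = 0.01, max_iter = 5000L, tol = 1e-8,
                        exclude_column = NULL) {
  stopifnot(inherits(d, "src"))
  y <- as.numeric(y)
  if (length(y) != d$m)
    stop_sparsebci("feature dimension ", length(y), " does not match dictionary m = ",
                   d$m, class = "sparsebci_validation_error")
  ynorm <- sqrt(sum(y^2))
  yn <- if (ynorm > 0) y / ynorm else y
  cols <- seq_len(d$N)
  if (!is.null(exclude_column)) cols <- cols[-exclude_column]
  sol <- solve_l1(d$A[, cols, drop = FALSE], yn, epsilon = epsilon,
                  max_iter = max_iter, tol = tol)
  x <- numeric(d$N)
  x[cols] <- sol$x
  res <- class_residuals(d, yn, x)
  structure(list(x_hat = x, residuals = res,
                 predicted_class = d$classes[which.min(res)],
                 l1_norm = sol$l1_norm, fit_residual = sol$fit_residual,
                 converged = sol$converged),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> class %d; residuals: %s; ||x||_1 = %.4g (%d nonzero)\n",
              x$predicted_class,
              paste(sprintf("%.4g", x$residuals), collapse = ", "),
              x$l1_norm, sum(x$x_hat != 0)))
  invisible(x)
}

#' Classify or encode feature vectors with a sparse-representation dictionary
#'
#' @param object an [src()] dictionary.
#' @param newx feature matrix (n x m), one row per sample. Rows are
#'   L2-normalized with the same convention as the dictionary columns.
#' @param type `"class"` for minimum-residual class labels, `"residuals"`
#'   for the n x k residual matrix, `"code"` for the n x N sparse-code
#'   matrix (the FCRes-CNN input representation), `"prob"` for softmin
#'   pseudo-probabilities derived from the residuals.
#' @param epsilon,max_iter,tol passed to [sparse_code()].
#' @param leave_one_out when `newx` rows are the training samples the
#'   dictionary was built from (in the same order), drop each sample's own
#'   column before coding it, so no sample is represented by itself.
#' @param ... unused.
#' @return Depends on `type`; see above.
#' @export
predict.src <- function(object, newx, type = c("class", "residuals", "code", "prob"),
                        epsilon = 0.01, max_iter = 5000L, tol = 1e-8,
                        leave_one_out = FALSE, ...) {
  type <- match.arg(type)
  newx <- if (is.null(dim(newx))) matrix(newx, 1L) else as.matrix(newx)
  n <- nrow(newx)
  if (leave_one_out && n != object$N)
    stop_sparsebci("leave-one-out coding requires one row per dictionary column",
                   class = "sparsebci_parameter_error")
  codes <- matrix(0, n, object$N)
  resid <- matrix(0, n, length(object$classes))
  labels <- integer(n)
  for (i in seq_len(n)) {
    sc <- sparse_code(object, newx[i, ], epsilon = epsilon, max_iter = max_iter,
                      tol = tol,
                      exclude_column = if (leave_one_out) object$row_to_column[i])
    codes[i, ] <- sc$x_hat
    resid[i, ] <- sc$residuals
    labels[i] <- sc$predicted_class
  }
  switch(type,
         class = labels,
         residuals = {colnames(resid) <- object$classes; resid},
         code = codes,
         prob = {
           p <- exp(-resid)
           p <- p / rowSums(p)
           colnames(p) <- object$classes
           p
         })
}

#' @rdname predict.src
#' @param x feature matrix to encode.
#' @export
sparse_codes <- function(object, x, epsilon = 0.01, leave_one_out = FALSE, ...)
  predict(object, x, type = "code", epsilon = epsilon,
          leave_one_out = leave_one_out, ...)
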