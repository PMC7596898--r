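# Shared fixtures and independent oracles used across the suite.

# two-class Gaussian feature blobs with well-separated means
make_feature_blobs <- function(n_per_class, m = 8L, sep = 3, seed = 1L) {
  set.seed(seed)
  mu1 <- rep(c(sep, 0), length.out = m)
  mu2 <- rep(c(0, sep), length.out = m)
  x <- rbind(sweep(matrix(rnorm(n_per_class * m), n_per_class), 2L, mu1, "+"),
             sweep(matrix(rnorm(n_per_class * m), n_per_class), 2L, mu2, "+"))
  list(x = x, labels = rep(1:2, each = n_per_class))
}

# epochs with exactly prescribed second moments: X %*% t(X) = C * scale
epochs_with_cov <- function(C_list, labels, fs = 100) {
  # orthonormal rows e_i over T = 4 samples
  E <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)) / 2
  dat <- lapply(C_list, function(C) {
    L <- t(chol(C))
    L %*% E
  })
  epoch_set(array(unlist(dat), dim = c(2L, 4L, length(C_list))), labels, fs)
}

# independent generalized-eigendecomposition oracle for a covariance pair:
# eigenvalues of C1 relative to C1 + C2
geigen_oracle <- function(C1, C2) {
  Cc <- C1 + C2
  ev <- eigen(Cc, symmetric = TRUE)
  P <- diag(1 / sqrt(ev$values), nrow(Cc)) %*% t(ev$vectors)
  sort(eigen(P %*% C1 %*% t(P), symmetric = TRUE)$values, decreasing = TRUE)
}

# exhaustive support-enumeration oracle for basis pursuit (exact solutions
# live on supports of size <= m); returns the optimal L1 value and support
bp_enumeration_oracle <- function(A, y, feas_tol = 1e-8) {
  N <- ncol(A); m <- nrow(A)
  best <- Inf; bsupp <- integer(0)
  for (s in seq_len(m)) {
    for (S in utils::combn(N, s, simplify = FALSE)) {
      fit <- tryCatch(qr.solve(A[, S, drop = FALSE], y), error = function(e) NULL)
      if (is.null(fit)) next
      if (sqrt(sum((A[, S, drop = FALSE] %*% fit - y)^2)) <= feas_tol &&
          sum(abs(fit)) < best) {
        best <- sum(abs(fit))
        bsupp <- S[abs(fit) > 1e-6]
      }
    }
  }
  list(l1 = best, supp = sort(bsupp))
}

random_bp_instance <- function(m = 6L, N = 12L, k = 2L) {
  A <- matrix(rnorm(m * N), m, N)
  A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  supp <- sample(N, k)
  x0 <- numeric(N)
  x0[supp] <- runif(k, 0.5, 2) * sample(c(-1, 1), k, replace = TRUE)
  list(A = A, x0 = x0, y = drop(A %*% x0), supp = sort(supp))
}

# sinusoidal single-channel epoch set for filter-response checks
tone_epochs <- function(freq, fs = 100, seconds = 3, n = 1L, label = 1L) {
  tt <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * tt)
  epoch_set(array(rep(x, n), dim = c(1L, length(tt), n)),
            rep(label, n), fs)
}

rms <- function(x) sqrt(mean(x^2))
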