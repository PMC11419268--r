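# Independent oracles used to cross-check the implementation.
# These deliberately take different numerical routes than the package:
# whitening by symmetric eigendecomposition inverse square roots + SVD for
# CCA, dense eigendecomposition of explicitly formed covariances for PCA,
# and an explicit projector for shared-variation removal.

# Whitening-SVD CCA over the sample space, constraint ||Xc a|| = 1.
oracle_cca <- function(xc, yc, k, ridge = 0) {
  m <- nrow(xc)
  sxx <- crossprod(xc) / m
  syy <- crossprod(yc) / m
  sxy <- crossprod(xc, yc) / m
  inv_sqrt <- function(s, r) {
    e <- eigen(s + diag(r, nrow(s)), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  }
  wx <- inv_sqrt(sxx, ridge * mean(diag(sxx)))
  wy <- inv_sqrt(syy, ridge * mean(diag(syy)))
  sv <- svd(wx %*% sxy %*% wy)
  a <- wx %*% sv$u[, seq_len(k), drop = FALSE]
  b <- wy %*% sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    a[, j] <- a[, j] / sqrt(sum((xc %*% a[, j])^2))
    b[, j] <- b[, j] / sqrt(sum((yc %*% b[, j])^2))
  }
  list(cor = sv$d[seq_len(k)], a = a, b = b)
}

# Brute-force PCA of a feature-by-sample matrix via the dense covariance.
oracle_pca <- function(xc, k) {
  cov <- tcrossprod(xc) / (ncol(xc) - 1L)
  e <- eigen(cov, symmetric = TRUE)
  list(loadings = e$vectors[, seq_len(k), drop = FALSE],
       eigenvalues = e$values[seq_len(k)])
}

# Explicit projector removal oracle.
oracle_remove <- function(xc, u0) {
  (diag(nrow(xc)) - tcrossprod(u0)) %*% xc
}

# Principal angles (radians) between the column spaces of two matrices.
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb), nu = 0L, nv = 0L)$d
  acos(pmin(pmax(sv, -1), 1))
}

# Random centered matrix helper.
rand_centered <- function(m, n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(m * n), m, n)
  sweep(x, 2L, colMeans(x), "-")
}

# Absolute correlation between a score column and a truth row.
abs_cor <- function(scores, truth_row) {
  abs(cor(as.vector(scores), as.vector(truth_row)))
}
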