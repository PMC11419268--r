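#' Sample-space canonical correlation analysis between cases and controls
#'
#' Finds pairs of sample-space coefficient vectors \eqn{(\hat a_r, \hat b_r)}
#' maximizing \eqn{a^\top X'^\top Y' b} subject to \eqn{\|X'a\|_2 = 1},
#' \eqn{\|Y'b\|_2 = 1}, with each new pair constrained so that \eqn{X'a_r}
#' (resp. \eqn{Y'b_r}) is orthogonal to all previous ones. Unlike textbook
#' CCA over features, the linear combinations here are taken over samples, so
#' each canonical variable \eqn{X'\hat a_r} is a direction in feature space:
#' the representation in the cases of a source of variation shared with the
#' controls.
#'
#' The solution is computed jointly from the eigendecomposition of the
#' regularized product matrix
#' \eqn{(S_{XX}+\epsilon I)^{-1} S_{XY} (S_{YY}+\epsilon I)^{-1} S_{YX}}
#' (via its symmetric Cholesky similarity transform), followed by
#' Gram-Schmidt re-orthonormalization of the canonical variables; covariances
#' are defined as \eqn{S_{XX} = X'^\top X'/m} and so on.
#'
#' @param xc,yc column-centered feature-by-sample matrices sharing the same
#'   m features (see [center_columns()]). The sample-space CCA requires more
#'   features than samples; use [rpaca()] when `m <= max(n0, n1)`.
#' @param k number of canonical pairs, `1 <= k <= min(n0, n1) - 1`.
#' @param ridge relative ridge stabilizer: `ridge * trace(S)/n` is added to
#'   the diagonal of each sample covariance before inversion. The default
#'   `1e-8` is a pure numerical safeguard, not a tuning parameter; set to 0
#'   for exact unregularized CCA on well-conditioned inputs.
#' @return An object of class `"paca_cca"`: a list with `a` (n1 x k), `b`
#'   (n0 x k) coefficient matrices and `cor`, the non-increasing canonical
#'   correlations in `[0, 1]`.
#' @examples
#' x <- center_columns(matrix(rnorm(200 * 10), 200))
#' y <- center_columns(matrix(rnorm(200 * 12), 200))
#' fit_cca(x, y, k = 2)$cor
#' @export
fit_cca <- function(xc, yc, k, ridge = 1e-8) {
  check_centered(xc, "xc")
  check_centered(yc, "yc")
  m <- nrow(xc)
  if (nrow(yc) != m) {
    stop(sprintf("`xc` and `yc` must share the feature dimension (%d vs %d)",
                 m, nrow(yc)), call. = FALSE)
  }
  n1 <- ncol(xc); n0 <- ncol(yc)
  if (m <= max(n0, n1)) {
    stop(errorCondition(
      sprintf(paste0("sample-space CCA requires more features than samples ",
                     "(m = %d, max(n0, n1) = %d); use rPACA (rpaca()) in this regime"),
              m, max(n0, n1)),
      class = c("paca_error_regime", "error", "condition")))
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > min(n0, n1) - 1L) {
    stop(sprintf("`k` must be an integer in [1, %d]", min(n0, n1) - 1L),
         call. = FALSE)
  }
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  res <- cca_core(crossprod(xc), crossprod(yc), crossprod(xc, yc), as.integer(k), ridge)
  structure(c(res, list(n1 = n1, n0 = n0, ridge = ridge)), class = "paca_cca")
}

# Core solver on the raw cross-product (Gram) matrices gxx = X'^T X', etc.
# The 1/m covariance factor cancels in the eigenproblem; the ridge is applied
# relative to the mean diagonal so results are scale-equivariant.
cca_core <- function(gxx, gyy, gxy, k, ridge) {
  n1 <- nrow(gxx); n0 <- nrow(gyy)
  rx <- ridge * mean(diag(gxx))
  ry <- ridge * mean(diag(gyy))
  Rx <- chol_named(gxx + diag(rx, n1), "S_XX")
  Ry <- chol_named(gyy + diag(ry, n0), "S_YY")
  # Symmetric similarity transform of S_XX^-1 S_XY S_YY^-1 S_YX:
  # N = L^-1 G_XY G_YY^-1 G_YX L^-T with G_XX = L L^T; eigenvalues are the
  # squared canonical correlations, a = L^-T u.
  H <- forwardsolve(t(Rx), gxy)        # n1 x n0
  Hy <- forwardsolve(t(Ry), t(H))      # n0 x n1
  N <- crossprod(Hy)
  e <- eigen((N + t(N)) / 2, symmetric = TRUE)
  lam <- pmin(pmax(e$values[seq_len(k)], 0), 1)
  a <- backsolve(Rx, e$vectors[, seq_len(k), drop = FALSE])
  # Normalize ||X'a_r|| = 1 and enforce the deflation constraints exactly by
  # Gram-Schmidt (Cholesky) in the unregularized X'^T X' metric.
  a <- gram_schmidt_metric(a, gxx, "case canonical variables")
  b <- backsolve(Ry, forwardsolve(t(Ry), crossprod(gxy, a)))
  b <- gram_schmidt_metric(b, gyy, "control canonical variables")
  # Align signs so each canonical pair correlates positively.
  d <- diag(crossprod(a, gxy %*% b))
  neg <- d < 0
  b[, neg] <- -b[, neg, drop = FALSE]
  list(a = a, b = b, cor = sqrt(lam))
}

chol_named <- function(s, name) {
  tryCatch(chol(s), error = function(e) {
    stop(sprintf("%s is rank-deficient and could not be factorized (%s); increase `ridge`",
                 name, conditionMessage(e)), call. = FALSE)
  })
}

gram_schmidt_metric <- function(a, g, what) {
  mg <- crossprod(a, g %*% a)
  r <- tryCatch(chol((mg + t(mg)) / 2), error = function(e) {
    stop(sprintf("deflation metric for %s is rank-deficient; reduce `k` or increase `ridge`",
                 what), call. = FALSE)
  })
  a %*% backsolve(r, diag(ncol(a)))
}

check_centered <- function(x, arg) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  check_finite(x, arg)
  tol <- 1e-10 * nrow(x) * max(1, max(abs(x)))
  if (max(abs(colSums(x))) > tol) {
    stop(sprintf("`%s` must be column-centered (see center_columns())", arg),
         call. = FALSE)
  }
  invisible(x)
}

#' Representation in the cases of the shared directions of variation
#'
#' Maps CCA sample-space coefficients to feature space:
#' \eqn{\hat U_0 = X' \hat A}, an orthonormal basis (given the CCA
#' constraints) of the case-side representation of the variation shared with
#' the controls.
#'
#' @param xc column-centered case matrix used in the CCA.
#' @param cca a `"paca_cca"` object from [fit_cca()], or `NULL` for `k = 0`.
#' @return An m x k matrix with orthonormal columns (m x 0 when `k = 0`).
#' @export
shared_basis <- function(xc, cca = NULL) {
  if (is.null(cca)) return(matrix(0, nrow(xc), 0L))
  a <- if (inherits(cca, "paca_cca")) cca$a else as.matrix(cca)
  if (ncol(a) == 0L) return(matrix(0, nrow(xc), 0L))
  if (ncol(xc) != nrow(a)) {
    stop(sprintf("`xc` has %d samples but the CCA coefficients have %d rows",
                 ncol(xc), nrow(a)), call. = FALSE)
  }
  xc %*% a
}

#' Remove shared variation from the centered case matrix
#'
#' Projects out the shared basis: \eqn{\tilde X = X' - U_0 U_0^\top X'}.
#' With `k = 0` (empty basis) the input is returned unchanged.
#'
#' @param xc column-centered case matrix.
#' @param u0 m x k orthonormal shared basis from [shared_basis()].
#' @return The m x n1 residual matrix, orthogonal to the columns of `u0`.
#' @export
remove_shared <- function(xc, u0) {
  if (nrow(u0) != nrow(xc)) {
    stop(sprintf("`u0` has %d rows but `xc` has %d features", nrow(u0), nrow(xc)),
         call. = FALSE)
  }
  if (ncol(u0) == 0L) return(xc)
  xc - u0 %*% crossprod(u0, xc)
}

#' PCA of the shared-variation-purged case matrix
#'
#' Computes the top `k1` principal component loadings and scores of the
#' residual case matrix. Loadings are orthonormal feature-space directions;
#' scores are the unnormalized projections \eqn{\tilde X^\top U_1} (not
#' unit-variance singular vectors), so that applying the loadings to new
#' data is a plain matrix product. Eigenvalues are those of the residual
#' feature-space covariance \eqn{\tilde X \tilde X^\top / (n_1 - 1)}. Each
#' loading column's sign is fixed so its entry of largest absolute value is
#' positive.
#'
#' @param x_tilde m x n1 residual matrix from [remove_shared()].
#' @param k1 number of components, `1 <= k1 <= min(m, n1) - 1`.
#' @return A list with `loadings` (m x k1), `scores` (n1 x k1),
#'   `eigenvalues` (length k1, non-increasing) and `var_total`, the total
#'   residual variance (sum of all covariance eigenvalues).
#' @export
residual_pca <- function(x_tilde, k1) {
  m <- nrow(x_tilde); n1 <- ncol(x_tilde)
  if (!is.numeric(k1) || length(k1) != 1L || k1 < 1L || k1 > min(m, n1) - 1L) {
    stop(sprintf("`k1` must be an integer in [1, %d]", min(m, n1) - 1L),
         call. = FALSE)
  }
  if (max(abs(x_tilde)) == 0) {
    stop("no residual variation: the residual matrix is identically zero",
         call. = FALSE)
  }
  k1 <- as.integer(k1)
  sv <- svd(x_tilde, nu = k1, nv = 0L)
  sgn <- fix_signs(sv$u)
  loadings <- sgn$loadings
  rownames(loadings) <- rownames(x_tilde)
  colnames(loadings) <- sprintf("PACA%d", seq_len(k1))
  scores <- crossprod(x_tilde, loadings)
  eig <- sv$d^2 / (n1 - 1)
  list(loadings = loadings,
       scores = scores,
       eigenvalues = eig[seq_len(k1)],
       var_total = sum(eig))
}
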