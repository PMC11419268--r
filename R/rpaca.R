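#' Randomized PACA for the more-samples-than-features regime
#'
#' The sample-space CCA at the heart of [paca()] requires more features than
#' samples in either group. When `max(n0, n1) >= m`, `rpaca()` estimates the
#' case-specific subspace by repeated subsampling: each resample draws
#' `subsample_size` case columns and the same number of control columns
#' without replacement (restoring the `m > n` regime), runs the full PACA
#' pipeline, and contributes its residual loadings \eqn{U_1^{(r)}}. The
#' resample fits are aggregated through the mean projection operator
#' \eqn{\bar P = \frac1R \sum_r U_1^{(r)} U_1^{(r)\top}}, whose top `k1`
#' eigenvectors form the consensus loadings — averaging projectors rather
#' than raw loadings sidesteps the sign and rotation ambiguity of individual
#' fits. Final scores project all centered case samples onto the consensus
#' loadings.
#'
#' @inheritParams paca
#' @param n_resamples number of random resamples (with `n_resamples = 1` the
#'   result is exactly the single subsample's fit projected to all cases).
#' @param subsample_size samples drawn per group in each resample; must
#'   satisfy `k + k1 + 2 <= subsample_size < m`. Defaults to
#'   `min(m - 1, min(n0, n1), floor(0.6 * m))`.
#' @param seed integer seed; the same seed reproduces the fit bitwise.
#' @return An object of class `c("rpaca", "paca")` supporting
#'   [predict.paca()]; `eigenvalues` holds the consensus score variances and
#'   `consensus_stability` the top eigenvalues of the mean projector (in
#'   `[0, 1]`; values near 1 indicate a stable subspace across resamples).
#' @examples
#' sim <- simulate_paca_data(m = 80, n1 = 150, n0 = 150, k0 = 1, k1 = 1,
#'                           shared_scales = 70, case_scales = 7, seed = 2)
#' fit <- rpaca(sim$x, sim$y, k = 1, k1 = 1, n_resamples = 10, seed = 5)
#' abs(cor(fit$scores[, 1], sim$z_x1[1, ]))
#' @export
rpaca <- function(X, Y, k, k1 = 2, n_resamples = 30, subsample_size = NULL,
                  ridge = 1e-8, seed = 1) {
  cl <- match.call()
  X <- as_data_matrix(X, "X")
  Y <- as_data_matrix(Y, "Y")
  check_same_features(X, Y)
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  if (m > max(n0, n1)) {
    stop(errorCondition(
      sprintf(paste0("m = %d exceeds both group sizes (n1 = %d, n0 = %d): ",
                     "the standard fit applies; use paca()"), m, n1, n0),
      class = c("paca_error_regime", "error", "condition")))
  }
  if (n_resamples < 1L) stop("`n_resamples` must be at least 1", call. = FALSE)
  if (is.null(subsample_size)) {
    subsample_size <- min(m - 1L, min(n0, n1), floor(0.6 * m))
  }
  s <- as.integer(subsample_size)
  if (s < k + k1 + 2L) {
    stop(sprintf("`subsample_size` must be at least k + k1 + 2 = %d", k + k1 + 2L),
         call. = FALSE)
  }
  if (s >= m) {
    stop("`subsample_size` must be smaller than the number of features",
         call. = FALSE)
  }
  if (s > min(n0, n1)) {
    stop("`subsample_size` cannot exceed the smaller group size", call. = FALSE)
  }

  R <- as.integer(n_resamples)
  proj_sum <- matrix(0, m, m)
  last_u1 <- NULL
  idx <- vector("list", R)
  with_seed(seed, {
    for (r in seq_len(R)) {
      ix <- sample.int(n1, s)
      iy <- sample.int(n0, s)
      idx[[r]] <- list(cases = ix, controls = iy)
      fit <- paca(X[, ix, drop = FALSE], Y[, iy, drop = FALSE],
                  k = k, k1 = k1, ridge = ridge)
      last_u1 <- fit$u1
      proj_sum <- proj_sum + tcrossprod(fit$u1)
    }
  })

  if (R == 1L) {
    u1 <- last_u1
    stability <- rep(1, k1)
  } else {
    e <- eigen(proj_sum / R, symmetric = TRUE)
    u1 <- fix_signs(e$vectors[, seq_len(k1), drop = FALSE])$loadings
    stability <- e$values[seq_len(k1)]
  }
  rownames(u1) <- rownames(X)
  colnames(u1) <- sprintf("PACA%d", seq_len(k1))
  xc <- sweep(X, 2L, colMeans(X), "-")
  scores <- crossprod(xc, u1)

  structure(list(
    call = cl,
    feature_ids = rownames(X),
    sample_ids = colnames(X),
    control_ids = colnames(Y),
    k = as.integer(k),
    k1 = as.integer(k1),
    ridge = ridge,
    centering = "per_sample_over_features",
    center_features = FALSE,
    feature_means = NULL,
    sign_convention = "max_abs_positive",
    u0 = matrix(0, m, 0L),
    u1 = u1,
    eigenvalues = apply(scores, 2L, stats::var),
    consensus_stability = stability,
    scores = scores,
    n_resamples = R,
    subsample_size = s,
    resample_indices = idx,
    seed = seed,
    version = paca_version()
  ), class = c("rpaca", "paca"))
}

#' @export
print.rpaca <- function(x, ...) {
  cat("Randomized phenotype-aware component analysis (rPACA)\n")
  cat(sprintf("  features: %d   cases: %d   controls: %d\n",
              length(x$feature_ids), length(x$sample_ids),
              length(x$control_ids)))
  cat(sprintf("  k = %d, k1 = %d, %d resamples of %d samples per group (seed %s)\n",
              x$k, x$k1, x$n_resamples, x$subsample_size,
              format(x$seed)))
  cat("  consensus stability: ",
      paste(sprintf("%.3f", x$consensus_stability), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
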