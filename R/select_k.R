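#' Permutation selection of the number of shared directions to remove
#'
#' Chooses the minimal number of canonical directions `k` whose removal
#' leaves significant case-specific structure. For each `k = 0, ..., k_max`
#' the full pipeline (centering, sample-space CCA, removal, residual PCA) is
#' run and the test statistic is the share of residual case variance carried
#' by the top residual component,
#' \eqn{t(k) = \lambda_1(\tilde X_k) / \sum_j \lambda_j(\tilde X_k)}.
#' The null distribution is obtained by pooling all case and control samples
#' and rerunning the pipeline on random relabelings that preserve the group
#' sizes; `p(k) = (1 + #\{null \ge observed\}) / (n_permutations + 1)`.
#'
#' A significant `t(k)` alone can reflect shared structure that removal at
#' small `k` missed, so a second, case-specificity condition is required:
#' the variance of the controls projected onto the top residual loading must
#' be significantly *small* against its own permutation null (lower-tail
#' permutation p-value `<= alpha`). `chosen_k` is the minimal `k` passing
#' both conditions, or `NA` ("none significant") if no `k` qualifies.
#'
#' One master seed generates one relabeling per permutation index, shared
#' across all `k`; statistics reported for smaller `k` therefore do not
#' change when `k_max` is enlarged.
#'
#' @inheritParams paca
#' @param k_max largest `k` considered; at most `min(n0, n1) - 2`.
#' @param n_permutations number of label permutations (at least 99; with 99
#'   permutations the smallest attainable p-value is 0.01).
#' @param alpha significance level for both conditions (default 0.05).
#' @param seed integer master seed for the permutation stream.
#' @return An object of class `"paca_kselect"`: a list with `chosen_k`
#'   (integer or `NA`), `per_k` (data frame with `k`, `statistic`,
#'   `p_value`, `control_stat`, `control_p`), `null_quantiles`
#'   (per-k quantiles of the permutation null of the statistic), `alpha`,
#'   `n_permutations` and `seed`.
#' @examples
#' sim <- simulate_paca_data(m = 300, n1 = 40, n0 = 40, k0 = 1, k1 = 1,
#'                           shared_scales = 70, case_scales = 20, seed = 3)
#' sel <- select_k(sim$x, sim$y, k_max = 2, n_permutations = 99, seed = 1)
#' sel$chosen_k
#' @export
select_k <- function(X, Y, k_max, n_permutations = 99, alpha = 0.05,
                     ridge = 1e-8, seed = 1) {
  X <- as_data_matrix(X, "X")
  Y <- as_data_matrix(Y, "Y")
  check_same_features(X, Y)
  m <- nrow(X); n1 <- ncol(X); n0 <- ncol(Y)
  if (m <= max(n0, n1)) {
    stop(errorCondition(
      "select_k() requires more features than samples in each group; use rpaca()",
      class = c("paca_error_regime", "error", "condition")))
  }
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max < 0L ||
      k_max > min(n0, n1) - 2L) {
    stop(sprintf("`k_max` must be an integer in [0, %d]", min(n0, n1) - 2L),
         call. = FALSE)
  }
  if (n_permutations < 99L) {
    stop("`n_permutations` must be at least 99", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  k_max <- as.integer(k_max)
  B <- as.integer(n_permutations)

  pooled <- cbind(sweep(X, 2L, colMeans(X), "-"),
                  sweep(Y, 2L, colMeans(Y), "-"))
  if (max(abs(pooled)) == 0) {
    stop("pooled matrix is constant: no variation to analyse", call. = FALSE)
  }
  G <- crossprod(pooled)
  n <- n1 + n0

  obs <- residual_stats_gram(G, seq_len(n1), n1 + seq_len(n0), k_max, ridge)
  perms <- with_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
  null_t <- matrix(NA_real_, B, k_max + 1L)
  null_c <- matrix(NA_real_, B, k_max + 1L)
  for (b in seq_len(B)) {
    i1 <- perms[[b]][seq_len(n1)]
    i0 <- perms[[b]][n1 + seq_len(n0)]
    s <- residual_stats_gram(G, i1, i0, k_max, ridge)
    null_t[b, ] <- s$t
    null_c[b, ] <- s$control
  }

  p_value <- vapply(seq_len(k_max + 1L), function(j) {
    (1 + sum(null_t[, j] >= obs$t[j])) / (B + 1)
  }, numeric(1L))
  control_p <- vapply(seq_len(k_max + 1L), function(j) {
    (1 + sum(null_c[, j] <= obs$control[j])) / (B + 1)
  }, numeric(1L))
  ok <- p_value <= alpha & control_p <= alpha
  chosen_k <- if (any(ok)) (which(ok)[1L] - 1L) else NA_integer_

  per_k <- data.frame(k = 0:k_max, statistic = obs$t, p_value = p_value,
                      control_stat = obs$control, control_p = control_p)
  probs <- c(0.5, 0.9, 0.95, 0.99)
  null_quantiles <- t(apply(null_t, 2L, stats::quantile, probs = probs))
  dimnames(null_quantiles) <- list(paste0("k=", 0:k_max),
                                   paste0("q", probs * 100))
  structure(list(chosen_k = chosen_k, per_k = per_k,
                 null_quantiles = null_quantiles, alpha = alpha,
                 n_permutations = B, seed = seed),
            class = "paca_kselect")
}

# Residual-PCA statistics for every k in 0..k_max for one labeling, computed
# entirely in the pooled sample space from the Gram matrix G of the pooled
# column-centered data (column centering commutes with relabeling).
# Returns t(k) = lambda_1 / sum(lambda) of the residual case matrix and the
# variance of the controls projected onto the top residual loading.
residual_stats_gram <- function(G, i1, i0, k_max, ridge) {
  gxx <- G[i1, i1, drop = FALSE]
  gyy <- G[i0, i0, drop = FALSE]
  gxy <- G[i1, i0, drop = FALSE]
  gyx <- t(gxy)
  n0 <- length(i0)
  A <- if (k_max > 0L) cca_core(gxx, gyy, gxy, k_max, ridge)$a else NULL
  t_stat <- numeric(k_max + 1L)
  c_stat <- numeric(k_max + 1L)
  for (k in 0:k_max) {
    if (k == 0L) {
      S <- gxx
      yxt <- gyx
    } else {
      ak <- A[, seq_len(k), drop = FALSE]
      tk <- gxx %*% ak
      S <- gxx - tcrossprod(tk)
      yxt <- gyx - (gyx %*% ak) %*% t(tk)
    }
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    if (lam[1L] <= 0) {
      t_stat[k + 1L] <- 0
      c_stat[k + 1L] <- Inf
    } else {
      t_stat[k + 1L] <- lam[1L] / sum(lam)
      w <- yxt %*% e$vectors[, 1L]
      c_stat[k + 1L] <- sum(w^2) / (lam[1L] * (n0 - 1))
    }
  }
  list(t = t_stat, control = c_stat)
}

#' @export
print.paca_kselect <- function(x, ...) {
  cat(sprintf("Permutation selection of k (%d permutations, alpha = %g)\n",
              x$n_permutations, x$alpha))
  print(transform(x$per_k,
                  statistic = round(statistic, 4),
                  control_stat = round(control_stat, 4)),
        row.names = FALSE)
  if (is.na(x$chosen_k)) {
    cat("chosen k: none significant\n")
  } else {
    cat(sprintf("chosen k: %d\n", x$chosen_k))
  }
  invisible(x)
}
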