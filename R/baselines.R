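#' Standard PCA baseline on the case matrix
#'
#' PCA of the column-centered case matrix under the same centering, score
#' and sign conventions as [paca()]; identical to `paca()` with `k = 0`.
#'
#' @inheritParams paca
#' @param k number of components.
#' @return A list with `loadings` (m x k), `scores` (n x k) and
#'   `eigenvalues` (of the feature-space covariance, non-increasing).
#' @export
pca_baseline <- function(X, k) {
  X <- as_data_matrix(X, "X")
  xc <- sweep(X, 2L, colMeans(X), "-")
  pc <- residual_pca(xc, k)
  list(loadings = pc$loadings, scores = pc$scores,
       eigenvalues = pc$eigenvalues, var_total = pc$var_total)
}

#' Contrastive PCA baseline
#'
#' Computes the top `k` eigenvectors of \eqn{C_X - \alpha C_Y}, where
#' \eqn{C_X}, \eqn{C_Y} are the feature-space covariances of the centered
#' case and control matrices. cPCA requires choosing the contrastive
#' hyperparameter \eqn{\alpha}: with \eqn{\alpha = 0} it reduces to plain
#' PCA of the cases, while very large \eqn{\alpha} drives the solution
#' toward the minimum-variance directions of the controls; no single value
#' is correct a priori, which is the failure mode PACA's parameter-free
#' construction avoids.
#'
#' @inheritParams paca
#' @param alpha non-negative contrastive hyperparameter.
#' @param k number of components, at most m.
#' @return An object of class `"cpca"`: list with `alpha`, `loadings`
#'   (m x k, orthonormal, sign-fixed), `eigenvalues` (non-increasing, may be
#'   negative for large alpha) and `scores` (`t(centered X) %*% loadings`).
#' @examples
#' sim <- simulate_paca_data(m = 100, n1 = 30, n0 = 30, seed = 1)
#' cp <- cpca(sim$x, sim$y, alpha = 1, k = 2)
#' head(cp$eigenvalues)
#' @export
cpca <- function(X, Y, alpha, k) {
  X <- as_data_matrix(X, "X")
  Y <- as_data_matrix(Y, "Y")
  check_same_features(X, Y)
  if (alpha < 0) stop("`alpha` must be non-negative", call. = FALSE)
  m <- nrow(X)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > m) {
    stop(sprintf("`k` must be an integer in [1, %d]", m), call. = FALSE)
  }
  xc <- sweep(X, 2L, colMeans(X), "-")
  yc <- sweep(Y, 2L, colMeans(Y), "-")
  cx <- tcrossprod(xc) / (ncol(X) - 1L)
  cy <- tcrossprod(yc) / (ncol(Y) - 1L)
  e <- eigen(cx - alpha * cy, symmetric = TRUE)
  loadings <- fix_signs(e$vectors[, seq_len(k), drop = FALSE])$loadings
  rownames(loadings) <- rownames(X)
  colnames(loadings) <- sprintf("cPC%d", seq_len(k))
  structure(list(alpha = alpha, loadings = loadings,
                 eigenvalues = e$values[seq_len(k)],
                 scores = crossprod(xc, loadings)),
            class = "cpca")
}

#' @export
print.cpca <- function(x, ...) {
  cat(sprintf("Contrastive PCA (alpha = %g): %d component(s) over %d features\n",
              x$alpha, ncol(x$loadings), nrow(x$loadings)))
  cat("  eigenvalues: ", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Ground-truth recovery report for estimated components
#'
#' Quantifies how well estimated component scores recover known simulated
#' factor activities: for each ground-truth factor, the best absolute
#' Pearson correlation over the estimated components, the multiple R-squared
#' of the truth regressed on all estimated components, and the largest
#' principal angle between the two score subspaces. All measures are
#' invariant to sign flips and, for R-squared and the angle, to invertible
#' linear mixing of the components.
#'
#' @param estimated n x k matrix of estimated component scores.
#' @param truth k_true x n matrix of true factor activities (factors in
#'   rows, matching the score rows' samples).
#' @return An object of class `"paca_recovery"`: list with `per_component`
#'   (data frame of `component`, `abs_r`, `r_squared`) and `subspace_angle`
#'   in radians.
#' @export
recovery_score <- function(estimated, truth) {
  estimated <- as.matrix(estimated)
  truth <- as.matrix(truth)
  if (nrow(estimated) != ncol(truth)) {
    stop(sprintf("estimated has %d samples but truth has %d columns",
                 nrow(estimated), ncol(truth)), call. = FALSE)
  }
  if (any(apply(estimated, 2L, stats::sd) == 0) ||
      any(apply(truth, 1L, stats::sd) == 0)) {
    stop("zero-variance component supplied to recovery_score()", call. = FALSE)
  }
  cors <- abs(stats::cor(t(truth), estimated))
  per <- data.frame(
    component = seq_len(nrow(truth)),
    abs_r = apply(cors, 1L, max),
    r_squared = vapply(seq_len(nrow(truth)), function(i) {
      # perfect fits are routine here (noiseless recovery); silence lm's
      # "essentially perfect fit" advisory
      suppressWarnings(summary(stats::lm(truth[i, ] ~ estimated))$r.squared)
    }, numeric(1L))
  )
  qe <- qr.Q(qr(estimated))
  qt <- qr.Q(qr(t(truth)))
  sv <- svd(crossprod(qe, qt), nu = 0L, nv = 0L)$d
  angle <- max(acos(pmin(pmax(sv, -1), 1)))
  structure(list(per_component = per, subspace_angle = angle),
            class = "paca_recovery")
}

#' @export
print.paca_recovery <- function(x, ...) {
  cat("Component recovery vs ground truth\n")
  print(transform(x$per_component,
                  abs_r = round(abs_r, 4),
                  r_squared = round(r_squared, 4)),
        row.names = FALSE)
  cat(sprintf("largest principal angle: %.4f rad\n", x$subspace_angle))
  invisible(x)
}

#' Simulation benchmark of PACA against PCA and cPCA
#'
#' For each simulation configuration and replicate, draws a dataset with
#' [simulate_paca_data()], fits the requested methods, and scores recovery
#' of the true case-specific factors with [recovery_score()]. For null
#' configurations (`k1 = 0`), recovery is undefined; optionally, a
#' [select_k()] false-positive indicator is recorded instead, giving the
#' empirical calibration of the permutation selection.
#'
#' @param configs a single configuration (named list of
#'   [simulate_paca_data()] arguments) or a list of such configurations.
#' @param methods subset of `c("paca", "pca", "cpca")`.
#' @param replicates simulated replicates per configuration.
#' @param seed master seed; replicate seeds are drawn deterministically
#'   from it, so the full result table is reproducible.
#' @param cpca_alpha contrastive hyperparameter(s) used for the cPCA rows.
#' @param run_select_k record `select_k()` rejection indicators on null
#'   configurations (slower).
#' @param k_max,n_permutations,alpha passed to [select_k()] when
#'   `run_select_k = TRUE`.
#' @return A data frame with one row per (configuration, replicate, method,
#'   component): columns `config`, `replicate`, `method`, `component`,
#'   `abs_r`, `r_squared`, `subspace_angle`, `chosen_k`, `rejected`.
#' @export
run_benchmark <- function(configs, methods = c("paca", "pca", "cpca"),
                          replicates = 5, seed = 1, cpca_alpha = 0.1,
                          run_select_k = FALSE, k_max = 2,
                          n_permutations = 99, alpha = 0.05) {
  if (!is.list(configs)) stop("`configs` must be a (list of) named list(s)")
  if (length(configs) == 0L || !is.list(configs[[1L]])) {
    configs <- list(configs)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  n_cells <- length(configs) * replicates
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_cells))
  rows <- list()
  cell <- 0L
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (r in seq_len(replicates)) {
      cell <- cell + 1L
      sim <- do.call(simulate_paca_data, c(cfg, list(seed = seeds[cell])))
      k0 <- sim$config$k0; k1 <- sim$config$k1
      is_null <- k1 == 0L
      if (!is_null) {
        for (method in methods) {
          scores <- switch(method,
            paca = paca(sim$x, sim$y, k = k0, k1 = max(1L, k1))$scores,
            pca = pca_baseline(sim$x, k = max(1L, k1))$scores,
            cpca = cpca(sim$x, sim$y, alpha = cpca_alpha,
                        k = max(1L, k1))$scores)
          rec <- recovery_score(scores, sim$z_x1)
          rows[[length(rows) + 1L]] <- data.frame(
            config = ci, replicate = r, method = method,
            component = rec$per_component$component,
            abs_r = rec$per_component$abs_r,
            r_squared = rec$per_component$r_squared,
            subspace_angle = rec$subspace_angle,
            chosen_k = NA_integer_, rejected = NA)
        }
      }
      if (is_null && run_select_k) {
        sel <- select_k(sim$x, sim$y, k_max = k_max,
                        n_permutations = n_permutations, alpha = alpha,
                        seed = seeds[cell])
        rows[[length(rows) + 1L]] <- data.frame(
          config = ci, replicate = r, method = "select_k",
          component = NA_integer_, abs_r = NA_real_, r_squared = NA_real_,
          subspace_angle = NA_real_, chosen_k = sel$chosen_k,
          rejected = !is.na(sel$chosen_k))
      }
    }
  }
  do.call(rbind, rows)
}
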