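#' Phenotype-aware component analysis of a case/control pair of matrices
#'
#' Fits the PACA model: both matrices are column-centered (each sample's mean
#' over features is subtracted), a sample-space canonical correlation
#' analysis identifies the `k` strongest directions of variation shared
#' between cases and controls, the shared basis \eqn{\hat U_0} is projected
#' out of the cases, and a PCA of the residual yields `k1` case-specific
#' loadings \eqn{\hat U_1} and per-case scores. The underlying model is a
#' low-rank factor decomposition
#' \eqn{X = W_0 Z_X^0 + W_1 Z_X^1 + E_X}, \eqn{Y = W_0 Z_Y^0 + E_Y} with
#' \eqn{W_0 \perp W_1}: the shared factors \eqn{W_0} (cell composition,
#' batch, ancestry, ...) typically dominate, while the case-only factors
#' \eqn{W_1} carry the phenotypic heterogeneity of interest. PACA has no
#' contrastive tuning parameter; the single structural choice, `k`, can be
#' selected by permutation with [select_k()].
#'
#' Scores are defined as \eqn{X'^\top \hat U_1}, so a fitted model applies to
#' a replication cohort by multiplying the same loadings onto the same
#' features — see [predict.paca()].
#'
#' @param X numeric feature-by-sample case matrix with feature ids as
#'   rownames and sample ids as colnames.
#' @param Y control matrix over the identical ordered feature set (use
#'   [align_features()] first if needed).
#' @param k number of shared canonical directions to remove; `k = 0` reduces
#'   PACA to a plain PCA of the centered case matrix.
#' @param k1 number of case-specific components to return (default 2; the
#'   patient stratification score is typically one chosen column of the
#'   score matrix).
#' @param ridge relative ridge stabilizer for the CCA, see [fit_cca()].
#' @param center_features optionally subtract each feature's mean (computed
#'   on each matrix separately) before the per-sample centering; off by
#'   default. The case feature means are stored so [predict.paca()] replays
#'   the identical convention.
#' @return An object of class `"paca"`; a list with components including
#'   `u0` (m x k shared basis), `u1` (m x k1 residual loadings),
#'   `eigenvalues` (residual covariance eigenvalues), `scores` (n1 x k1
#'   case scores), `cca` (canonical coefficients and correlations) and
#'   `residuals` (the m x n1 purged case matrix). Methods: `print`,
#'   `summary`, `coef` (loadings), `predict`, `plot`, `screeplot`,
#'   `residuals`.
#' @examples
#' sim <- simulate_paca_data(m = 300, n1 = 60, n0 = 60, k0 = 2, k1 = 1,
#'                           seed = 7)
#' fit <- paca(sim$x, sim$y, k = 2, k1 = 1)
#' fit
#' abs(cor(fit$scores[, 1], sim$z_x1[1, ]))
#' @seealso [select_k()], [rpaca()], [predict.paca()], [pca_baseline()],
#'   [cpca()]
#' @export
paca <- function(X, Y, k, k1 = 2, ridge = 1e-8, center_features = FALSE) {
  cl <- match.call()
  X <- as_data_matrix(X, "X")
  Y <- as_data_matrix(Y, "Y")
  check_same_features(X, Y)
  if (!is.numeric(k) || length(k) != 1L || k < 0L) {
    stop("`k` must be a non-negative integer", call. = FALSE)
  }
  k <- as.integer(k)

  feature_means <- NULL
  if (center_features) {
    cx <- center_rows(X)
    X <- cx$values
    feature_means <- cx$means
    Y <- center_rows(Y)$values
  }
  xc <- sweep(X, 2L, colMeans(X), "-")
  yc <- sweep(Y, 2L, colMeans(Y), "-")

  if (k == 0L) {
    cca <- NULL
    u0 <- matrix(0, nrow(xc), 0L)
  } else {
    cca <- fit_cca(xc, yc, k, ridge)
    u0 <- shared_basis(xc, cca)
  }
  x_tilde <- remove_shared(xc, u0)
  pc <- residual_pca(x_tilde, k1)
  # Score convention: project the centered cases (not the residual) onto the
  # loadings, the same product predict() applies to new cohorts. The two
  # agree up to the numerical orthogonality of u0 and u1.
  scores <- crossprod(xc, pc$loadings)

  structure(list(
    call = cl,
    feature_ids = rownames(X),
    sample_ids = colnames(X),
    control_ids = colnames(Y),
    k = k,
    k1 = as.integer(k1),
    ridge = ridge,
    centering = "per_sample_over_features",
    center_features = center_features,
    feature_means = feature_means,
    sign_convention = "max_abs_positive",
    cca = cca,
    u0 = u0,
    u1 = pc$loadings,
    eigenvalues = pc$eigenvalues,
    var_total = pc$var_total,
    scores = scores,
    residuals = x_tilde,
    version = paca_version()
  ), class = "paca")
}

check_same_features <- function(X, Y) {
  fx <- rownames(X); fy <- rownames(Y)
  if (identical(fx, fy)) return(invisible(TRUE))
  only_x <- setdiff(fx, fy); only_y <- setdiff(fy, fx)
  if (!length(only_x) && !length(only_y)) {
    stop(paste0("X and Y contain the same features in different orders; ",
                "call align_features() first"), call. = FALSE)
  }
  fmt <- function(v) paste(utils::head(v, 5L), collapse = ", ")
  stop(errorCondition(sprintf(
    "X and Y must share an identical ordered feature set; %d feature(s) only in X (%s), %d only in Y (%s); see align_features()",
    length(only_x), fmt(only_x), length(only_y), fmt(only_y)),
    class = c("paca_error_features", "error", "condition")))
}

#' Project new samples onto a fitted PACA model
#'
#' Applies the fitted case-specific loadings to a new cohort measured on the
#' same features: new samples are aligned to the model's feature order,
#' centered with the centering convention recorded in the model, and scores
#' are computed as `t(centered newdata) %*% u1` — the coefficients of the
#' components multiplied by the same features. Applying a model to its own
#' training matrix reproduces the training scores exactly.
#'
#' @param object a fitted `"paca"` (or `"rpaca"`) model.
#' @param newdata feature-by-sample matrix containing every model feature;
#'   extra features are dropped with a warning.
#' @param ... unused.
#' @return An n x k1 score matrix with the new sample ids as rownames.
#' @export
predict.paca <- function(object, newdata, ...) {
  newdata <- as_data_matrix(newdata, "newdata")
  missing <- setdiff(object$feature_ids, rownames(newdata))
  if (length(missing)) {
    stop(sprintf("newdata is missing %d model feature(s): %s",
                 length(missing),
                 paste(utils::head(missing, 10L), collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(rownames(newdata), object$feature_ids)
  if (length(extra)) {
    warning(sprintf("dropping %d feature(s) of newdata not in the model",
                    length(extra)), call. = FALSE)
  }
  x <- newdata[object$feature_ids, , drop = FALSE]
  if (isTRUE(object$center_features)) {
    x <- x - object$feature_means
  }
  xc <- sweep(x, 2L, colMeans(x), "-")
  crossprod(xc, object$u1)
}

#' @export
print.paca <- function(x, ...) {
  cat("Phenotype-aware component analysis\n")
  cat(sprintf("  features: %d   cases: %d   controls: %d\n",
              length(x$feature_ids), length(x$sample_ids),
              length(x$control_ids)))
  cat(sprintf("  shared directions removed (k): %d\n", x$k))
  cat(sprintf("  case-specific components (k1): %d\n", x$k1))
  if (!is.null(x$cca)) {
    cat("  canonical correlations: ",
        paste(sprintf("%.3f", x$cca$cor), collapse = ", "), "\n", sep = "")
  }
  cat("  residual variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$eigenvalues / x$var_total),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.paca <- function(object, ...) {
  out <- list(
    dims = c(m = length(object$feature_ids),
             n1 = length(object$sample_ids),
             n0 = length(object$control_ids)),
    k = object$k, k1 = object$k1,
    canonical_correlations = if (is.null(object$cca)) numeric(0) else object$cca$cor,
    eigenvalues = object$eigenvalues,
    prop_residual_var = object$eigenvalues / object$var_total,
    score_sd = apply(object$scores, 2L, stats::sd)
  )
  class(out) <- "summary.paca"
  out
}

#' @export
print.summary.paca <- function(x, ...) {
  cat(sprintf("PACA fit: m = %d features, n1 = %d cases, n0 = %d controls\n",
              x$dims["m"], x$dims["n1"], x$dims["n0"]))
  cat(sprintf("k = %d shared directions removed, k1 = %d components kept\n",
              x$k, x$k1))
  if (length(x$canonical_correlations)) {
    cat("Canonical correlations:\n")
    print(round(x$canonical_correlations, 4))
  }
  tab <- rbind(eigenvalue = x$eigenvalues,
               `residual var %` = 100 * x$prop_residual_var,
               `score sd` = x$score_sd)
  colnames(tab) <- sprintf("PACA%d", seq_along(x$eigenvalues))
  print(round(tab, 3))
  invisible(x)
}

#' Extract PACA loadings
#'
#' Returns the case-specific feature loadings \eqn{\hat U_1} (the
#' coefficients applied to features to form the scores).
#'
#' @param object a fitted `"paca"` model.
#' @param ... unused.
#' @export
coef.paca <- function(object, ...) object$u1

#' @export
residuals.paca <- function(object, ...) object$residuals

#' Scatterplot of PACA case scores
#'
#' @param x a fitted `"paca"` model.
#' @param components which two score columns to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.paca <- function(x, components = c(1L, 2L), ...) {
  s <- x$scores
  if (ncol(s) == 1L) {
    graphics::plot(seq_len(nrow(s)), s[, 1L], xlab = "case",
                   ylab = colnames(s)[1L], ...)
  } else {
    components <- components[seq_len(2L)]
    graphics::plot(s[, components[1L]], s[, components[2L]],
                   xlab = colnames(s)[components[1L]],
                   ylab = colnames(s)[components[2L]], ...)
  }
  invisible(x)
}

#' @export
screeplot.paca <- function(x, ...) {
  graphics::barplot(x$eigenvalues, names.arg = colnames(x$u1),
                    ylab = "residual covariance eigenvalue", ...)
  invisible(x)
}
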