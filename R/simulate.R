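#' Simulate a case/control dataset from the PACA generative model
#'
#' Draws data from the low-rank factor model
#' \deqn{X = W_0 Z_X^0 + W_1 Z_X^1 + E_X, \qquad Y = W_0 Z_Y^0 + E_Y,}
#' with orthonormal feature-space bases \eqn{W_0} (k0 shared factors) and
#' \eqn{W_1} (k1 case-only factors), Gaussian factor activities whose
#' per-row standard deviations are `shared_scales` / `case_scales`, and
#' i.i.d. Gaussian noise of standard deviation `sigma`. Because the `W`
#' columns are unit-norm, factor dominance is the single interpretable ratio
#' `shared_scales / case_scales`. The defaults emulate the regime the method
#' targets: dominant shared variation (cell composition, batch, ancestry
#' surrogates) an order of magnitude stronger than a subtle case-only factor
#' that is nonetheless detectable in aggregate across features.
#'
#' @param m,n1,n0 numbers of features, case samples, control samples.
#' @param k0,k1 numbers of shared and case-specific factors (either may be 0).
#' @param shared_scales,case_scales positive per-factor standard deviations
#'   of the shared / case-specific activity rows.
#' @param sigma noise standard deviation (may be 0 for noiseless draws).
#' @param orthogonal_w when `TRUE` (default) `W0` and `W1` are blocks of one
#'   orthonormal basis, enforcing the identifiability assumption
#'   \eqn{W_0 \perp W_1}; when `FALSE`, `W1` is drawn independently.
#' @param beta_squash map values through the logistic function into (0, 1)
#'   to emulate methylation beta values (ground-truth factors are kept on
#'   the pre-squash scale). Off by default: the model is unbounded Gaussian.
#' @param seed integer seed; identical configuration and seed give an
#'   identical dataset. The caller's RNG state is left untouched.
#' @return An object of class `"paca_sim"`: a list with matrices `x`
#'   (m x n1), `y` (m x n0), ground truth `w0`, `w1`, `z_x0`, `z_y0`,
#'   `z_x1`, and `config`.
#' @examples
#' sim <- simulate_paca_data(m = 200, n1 = 40, n0 = 40, seed = 1)
#' dim(sim$x)
#' @export
simulate_paca_data <- function(m = 1000, n1 = 200, n0 = 200, k0 = 3, k1 = 1,
                               shared_scales = rep(70, k0),
                               case_scales = rep(7, k1),
                               sigma = 1, orthogonal_w = TRUE,
                               beta_squash = FALSE, seed = 1) {
  stopifnot(m >= 2, n1 >= 2, n0 >= 2, k0 >= 0, k1 >= 0, sigma >= 0)
  if (k0 + k1 > min(m, n0, n1)) {
    stop("k0 + k1 must not exceed min(m, n0, n1)", call. = FALSE)
  }
  if (length(shared_scales) != k0 || (k0 && any(shared_scales <= 0))) {
    stop("`shared_scales` must be k0 positive values", call. = FALSE)
  }
  if (length(case_scales) != k1 || (k1 && any(case_scales <= 0))) {
    stop("`case_scales` must be k1 positive values", call. = FALSE)
  }
  config <- list(m = m, n1 = n1, n0 = n0, k0 = k0, k1 = k1,
                 shared_scales = shared_scales, case_scales = case_scales,
                 sigma = sigma, orthogonal_w = orthogonal_w,
                 beta_squash = beta_squash, seed = seed)
  with_seed(seed, {
    if (orthogonal_w) {
      w <- if (k0 + k1 > 0) {
        qr.Q(qr(matrix(stats::rnorm(m * (k0 + k1)), m)))
      } else matrix(0, m, 0L)
      w0 <- w[, seq_len(k0), drop = FALSE]
      w1 <- w[, k0 + seq_len(k1), drop = FALSE]
    } else {
      w0 <- if (k0) qr.Q(qr(matrix(stats::rnorm(m * k0), m))) else matrix(0, m, 0L)
      w1 <- if (k1) qr.Q(qr(matrix(stats::rnorm(m * k1), m))) else matrix(0, m, 0L)
    }
    z_x0 <- shared_scales * matrix(stats::rnorm(k0 * n1), k0, n1)
    z_y0 <- shared_scales * matrix(stats::rnorm(k0 * n0), k0, n0)
    z_x1 <- case_scales * matrix(stats::rnorm(k1 * n1), k1, n1)
    e_x <- matrix(stats::rnorm(m * n1, sd = sigma), m, n1)
    e_y <- matrix(stats::rnorm(m * n0, sd = sigma), m, n0)
    x <- w0 %*% z_x0 + w1 %*% z_x1 + e_x
    y <- w0 %*% z_y0 + e_y
    if (beta_squash) {
      x <- stats::plogis(x)
      y <- stats::plogis(y)
    }
    feats <- sprintf("cpg%06d", seq_len(m))
    dimnames(x) <- list(feats, sprintf("case_%04d", seq_len(n1)))
    dimnames(y) <- list(feats, sprintf("ctrl_%04d", seq_len(n0)))
    rownames(w0) <- rownames(w1) <- feats
    structure(list(x = x, y = y, w0 = w0, w1 = w1,
                   z_x0 = z_x0, z_y0 = z_y0, z_x1 = z_x1,
                   config = config),
              class = "paca_sim")
  })
}

#' Simulate a null case/control dataset (no case-specific factor)
#'
#' Convenience wrapper around [simulate_paca_data()] forcing `k1 = 0`, so
#' cases and controls are exchangeable: useful for calibration studies of
#' [select_k()].
#'
#' @inheritParams simulate_paca_data
#' @return A `"paca_sim"` object whose `w1` and `z_x1` blocks are empty.
#' @export
simulate_paca_null <- function(m = 1000, n1 = 200, n0 = 200, k0 = 3,
                               shared_scales = rep(70, k0), sigma = 1,
                               orthogonal_w = TRUE, beta_squash = FALSE,
                               seed = 1) {
  simulate_paca_data(m = m, n1 = n1, n0 = n0, k0 = k0, k1 = 0,
                     shared_scales = shared_scales,
                     case_scales = numeric(0), sigma = sigma,
                     orthogonal_w = orthogonal_w, beta_squash = beta_squash,
                     seed = seed)
}

#' Simulate a replication cohort sharing the factor bases of a simulation
#'
#' Draws new factor activities and noise but reuses `w0`, `w1`, the factor
#' scales, the noise level and the squash flag of an existing simulated
#' dataset, mimicking a second cohort measured on the same features and
#' governed by the same biology — the setting in which a fitted model's
#' loadings are transferred with [predict.paca()].
#'
#' @param sim a `"paca_sim"` object.
#' @param n1,n0 cohort sizes (default: same as `sim`).
#' @param seed integer seed for the new draws.
#' @return A `"paca_sim"` object with the same `w0`, `w1` as `sim`.
#' @export
simulate_replication <- function(sim, n1 = NULL, n0 = NULL, seed = 1) {
  stopifnot(inherits(sim, "paca_sim"))
  cfg <- sim$config
  if (is.null(n1)) n1 <- cfg$n1
  if (is.null(n0)) n0 <- cfg$n0
  with_seed(seed, {
    m <- cfg$m; k0 <- cfg$k0; k1 <- cfg$k1
    z_x0 <- cfg$shared_scales * matrix(stats::rnorm(k0 * n1), k0, n1)
    z_y0 <- cfg$shared_scales * matrix(stats::rnorm(k0 * n0), k0, n0)
    z_x1 <- cfg$case_scales * matrix(stats::rnorm(k1 * n1), k1, n1)
    x <- sim$w0 %*% z_x0 + sim$w1 %*% z_x1 +
      matrix(stats::rnorm(m * n1, sd = cfg$sigma), m, n1)
    y <- sim$w0 %*% z_y0 + matrix(stats::rnorm(m * n0, sd = cfg$sigma), m, n0)
    if (cfg$beta_squash) {
      x <- stats::plogis(x)
      y <- stats::plogis(y)
    }
    dimnames(x) <- list(rownames(sim$w0), sprintf("rep_case_%04d", seq_len(n1)))
    dimnames(y) <- list(rownames(sim$w0), sprintf("rep_ctrl_%04d", seq_len(n0)))
    cfg$n1 <- n1; cfg$n0 <- n0; cfg$seed <- seed
    structure(list(x = x, y = y, w0 = sim$w0, w1 = sim$w1,
                   z_x0 = z_x0, z_y0 = z_y0, z_x1 = z_x1, config = cfg),
              class = "paca_sim")
  })
}

#' @export
print.paca_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Simulated case/control dataset: m = %d features, ",
                     "n1 = %d cases, n0 = %d controls\n"),
              cfg$m, cfg$n1, cfg$n0))
  cat(sprintf("  k0 = %d shared factor(s), k1 = %d case-specific, sigma = %g, seed = %d\n",
              cfg$k0, cfg$k1, cfg$sigma, cfg$seed))
  invisible(x)
}
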