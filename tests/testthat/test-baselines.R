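sim_b <- simulate_paca_data(m = 120, n1 = 30, n0 = 30, k0 = 2, k1 = 1,
                            shared_scales = c(20, 20), case_scales = 5,
                            seed = 1101)

test_that("cPCA with alpha = 0 is plain PCA of the cases", {
  cp <- cpca(sim_b$x, sim_b$y, alpha = 0, k = 3)
  pb <- pca_baseline(sim_b$x, 3)
  expect_equal(abs(diag(crossprod(cp$loadings, pb$loadings))), rep(1, 3),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cPCA against a duplicate of the cases is still PCA of the cases", {
  cp <- cpca(sim_b$x, sim_b$x, alpha = 0.5, k = 2)
  pb <- pca_baseline(sim_b$x, 2)
  expect_equal(abs(diag(crossprod(cp$loadings, pb$loadings))), rep(1, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cPCA matches the dense eigendecomposition oracle", {
  set.seed(1102)
  x <- matrix(rnorm(60 * 25), 60)
  y <- matrix(rnorm(60 * 25), 60)
  rownames(x) <- rownames(y) <- paste0("f", 1:60)
  cp <- cpca(x, y, alpha = 2, k = 4)
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  e <- eigen(tcrossprod(xc) / 24 - 2 * tcrossprod(yc) / 24, symmetric = TRUE)
  expect_equal(cp$eigenvalues, e$values[1:4], tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(cp$loadings, e$vectors[, 1:4]))), rep(1, 4),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the PCA baseline matches the eigendecomposition oracle", {
  set.seed(1103)
  x <- matrix(rnorm(40 * 15), 40)
  pb <- pca_baseline(x, 3)
  xc <- sweep(x, 2, colMeans(x))
  orc <- oracle_pca(xc, 3)
  expect_equal(pb$eigenvalues, orc$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(pb$loadings, orc$loadings))), rep(1, 3),
               tolerance = 1e-8, ignore_attr = TRUE)
  # rank-1 input: one nonzero eigenvalue carrying all the variance
  r1 <- rnorm(40) %o% rnorm(15)
  pb1 <- pca_baseline(r1, 3)
  expect_equal(pb1$eigenvalues[1], pb1$var_total, tolerance = 1e-8)
  expect_lt(pb1$eigenvalues[2] / pb1$eigenvalues[1], 1e-10)
})

test_that("cPCA alpha extremes bracket PCA of X and min-variance of Y", {
  # alpha -> 0: cPCA subspace converges to the PCA subspace of X
  cp0 <- cpca(sim_b$x, sim_b$y, alpha = 1e-12, k = 2)
  pb <- pca_baseline(sim_b$x, 2)
  expect_lt(max(principal_angles(cp0$loadings, pb$loadings)), 1e-6)
  # very large alpha: top component aligns with the minimum-variance
  # eigenvector of C_Y (full-rank toy instance, m < n)
  set.seed(1104)
  x <- matrix(rnorm(10 * 50), 10)
  y <- matrix(rnorm(10 * 50), 10)
  rownames(x) <- rownames(y) <- paste0("f", 1:10)
  cp_inf <- cpca(x, y, alpha = 1e6, k = 1)
  yc <- sweep(y, 2, colMeans(y))
  ey <- eigen(tcrossprod(yc) / 49, symmetric = TRUE)
  vmin <- ey$vectors[, 10]
  expect_gt(abs(sum(cp_inf$loadings[, 1] * vmin)), 0.99)
})

test_that("recovery_score is exact and sign-invariant on perfect estimates", {
  set.seed(1105)
  truth <- matrix(rnorm(2 * 50), 2)
  r1 <- recovery_score(t(truth), truth)
  expect_equal(r1$per_component$abs_r, c(1, 1), tolerance = 1e-12)
  expect_equal(r1$per_component$r_squared, c(1, 1), tolerance = 1e-12)
  expect_lt(r1$subspace_angle, 1e-6)
  r2 <- recovery_score(-t(truth), truth)
  expect_equal(r1$per_component$abs_r, r2$per_component$abs_r)
  expect_equal(r1$subspace_angle, r2$subspace_angle, tolerance = 1e-10)
})

test_that("recovery of independent noise is near zero", {
  ok <- 0L
  for (seed in 1:20) {
    set.seed(1200 + seed)
    est <- matrix(rnorm(1000 * 2), 1000)
    truth <- matrix(rnorm(1 * 1000), 1)
    r <- recovery_score(est, truth)
    if (r$per_component$abs_r < 0.1 && r$per_component$r_squared < 0.02) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 19L)
  expect_error(recovery_score(matrix(1, 10, 1), matrix(rnorm(10), 1)),
               "zero-variance")
})

test_that("the benchmark table is reproducible and ranks PACA first", {
  cfg <- list(m = 300, n1 = 60, n0 = 60, k0 = 2, k1 = 1,
              shared_scales = c(70, 70), case_scales = 7, sigma = 1)
  b1 <- run_benchmark(cfg, replicates = 4, seed = 1301, cpca_alpha = 0.1)
  b2 <- run_benchmark(cfg, replicates = 4, seed = 1301, cpca_alpha = 0.1)
  expect_identical(b1, b2)
  means <- tapply(b1$abs_r, b1$method, mean)
  expect_gt(means[["paca"]], means[["pca"]])
  expect_gt(means[["paca"]], means[["cpca"]])
})

test_that("benchmark records select_k calibration on null configurations", {
  cfg <- list(m = 150, n1 = 25, n0 = 25, k0 = 1, k1 = 0,
              shared_scales = 30, case_scales = numeric(0), sigma = 1)
  b <- run_benchmark(cfg, replicates = 2, seed = 1302, run_select_k = TRUE,
                     k_max = 1)
  expect_identical(b$method, rep("select_k", 2))
  expect_type(b$rejected, "logical")
})
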