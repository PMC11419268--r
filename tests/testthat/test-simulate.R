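test_that("noiseless draws have the configured low rank", {
  sim <- simulate_paca_data(m = 120, n1 = 30, n0 = 30, k0 = 2, k1 = 0,
                            shared_scales = c(5, 3), case_scales = numeric(0),
                            sigma = 0, seed = 801)
  expect_lte(sum(svd(sim$x)$d > 1e-10), 2L)
  expect_lte(sum(svd(sim$y)$d > 1e-10), 2L)
})

test_that("the factor bases are orthonormal and mutually orthogonal", {
  sim <- simulate_paca_data(m = 200, n1 = 30, n0 = 30, k0 = 3, k1 = 2,
                            shared_scales = rep(10, 3), case_scales = c(2, 2),
                            seed = 802)
  expect_lt(max(abs(crossprod(sim$w0) - diag(3))), 1e-12)
  expect_lt(max(abs(crossprod(sim$w1) - diag(2))), 1e-12)
  expect_lt(max(abs(crossprod(sim$w0, sim$w1))), 1e-12)
})

test_that("the reconstructed noise variance matches sigma squared", {
  sim <- simulate_paca_data(m = 2000, n1 = 300, n0 = 300, k0 = 2, k1 = 1,
                            shared_scales = c(10, 10), case_scales = 2,
                            sigma = 1.5, seed = 803)
  resid <- sim$x - sim$w0 %*% sim$z_x0 - sim$w1 %*% sim$z_x1
  expect_equal(mean(resid^2), 1.5^2, tolerance = 0.02)
})

test_that("identical configuration and seed give identical datasets", {
  s1 <- simulate_paca_data(m = 100, n1 = 20, n0 = 25, seed = 804)
  s2 <- simulate_paca_data(m = 100, n1 = 20, n0 = 25, seed = 804)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$w1, s2$w1)
  s3 <- simulate_paca_data(m = 100, n1 = 20, n0 = 25, seed = 805)
  expect_false(identical(s1$x, s3$x))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(simulate_paca_data(m = 60, n1 = 10, n0 = 10, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("null simulations make cases and controls exchangeable", {
  # column norms are i.i.d. across samples within each group; under the
  # null both groups follow the same law, so a two-sample KS test should
  # reject at its nominal rate only
  rejections <- 0L
  for (seed in 1:30) {
    sim <- simulate_paca_null(m = 300, n1 = 60, n0 = 60, k0 = 2,
                              shared_scales = c(30, 30), seed = 900 + seed)
    p <- suppressWarnings(
      stats::ks.test(sqrt(colSums(sim$x^2)), sqrt(colSums(sim$y^2)))$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L)
})

test_that("null wrapper forces an empty case-specific block", {
  sim <- simulate_paca_null(m = 80, n1 = 15, n0 = 15, k0 = 2,
                            shared_scales = c(5, 5), seed = 806)
  expect_identical(ncol(sim$w1), 0L)
  expect_identical(nrow(sim$z_x1), 0L)
})

test_that("beta squashing maps values into (0, 1) and keeps the truth", {
  sim <- simulate_paca_data(m = 100, n1 = 20, n0 = 20, k0 = 1, k1 = 1,
                            shared_scales = 3, case_scales = 1,
                            beta_squash = TRUE, seed = 807)
  expect_true(all(sim$x > 0 & sim$x < 1))
  expect_true(all(sim$y > 0 & sim$y < 1))
  expect_identical(dim(sim$z_x1), c(1L, 20L))
})

test_that("recovery improves monotonically with the case-to-noise ratio", {
  grid <- c(1, 2, 4, 7, 12)
  mean_r <- vapply(seq_along(grid), function(g) {
    r <- vapply(1:3, function(rep) {
      sim <- simulate_paca_data(m = 400, n1 = 80, n0 = 80, k0 = 2, k1 = 1,
                                shared_scales = c(70, 70),
                                case_scales = grid[g], sigma = 1,
                                seed = 1000 + 10 * g + rep)
      fit <- paca(sim$x, sim$y, k = 2, k1 = 1)
      abs_cor(fit$scores[, 1], sim$z_x1[1, ])
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_gt(cor(seq_along(grid), mean_r, method = "spearman"), 0.89)
  expect_gt(mean_r[5], mean_r[1])
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_paca_data(m = 10, n1 = 5, n0 = 5, k0 = 4, k1 = 3),
               "k0 \\+ k1")
  expect_error(simulate_paca_data(m = 50, n1 = 10, n0 = 10, k0 = 2, k1 = 0,
                                  shared_scales = c(1, -1),
                                  case_scales = numeric(0)),
               "shared_scales")
})
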