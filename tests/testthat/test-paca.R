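sim_small <- simulate_paca_data(m = 300, n1 = 50, n0 = 60, k0 = 2, k1 = 1,
                                shared_scales = c(70, 70), case_scales = 7,
                                sigma = 1, seed = 101)

test_that("paca with k = 0 reduces exactly to PCA of the centered cases", {
  fit <- paca(sim_small$x, sim_small$y, k = 0, k1 = 3)
  pb <- pca_baseline(sim_small$x, 3)
  expect_lt(max(abs(fit$scores - pb$scores)), 1e-10)
  expect_equal(fit$eigenvalues, pb$eigenvalues, tolerance = 1e-10)
})

test_that("noiseless orthogonal simulation is recovered exactly", {
  sim <- simulate_paca_data(m = 200, n1 = 40, n0 = 40, k0 = 1, k1 = 1,
                            shared_scales = 10, case_scales = 1, sigma = 0,
                            seed = 7)
  fit <- paca(sim$x, sim$y, k = 1, k1 = 1)
  expect_gt(abs_cor(fit$scores[, 1], sim$z_x1[1, ]), 0.999)
})

test_that("the fitted model satisfies the residual-orthogonality invariant", {
  fit <- paca(sim_small$x, sim_small$y, k = 2, k1 = 2)
  xc <- center_columns(sim_small$x)
  expect_lte(max(abs(crossprod(fit$u0, residuals(fit)))),
             1e-10 * sqrt(sum(xc^2)))
  expect_lt(max(abs(crossprod(fit$u0, fit$u1))), 1e-6)
  expect_lt(max(abs(crossprod(fit$u1) - diag(2))), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 0))
})

test_that("PACA finds the subtle case factor where PCA tracks the background", {
  fit <- paca(sim_small$x, sim_small$y, k = 2, k1 = 1)
  pb <- pca_baseline(sim_small$x, 1)
  expect_gt(abs_cor(fit$scores[, 1], sim_small$z_x1[1, ]), 0.9)
  expect_lt(abs_cor(pb$scores[, 1], sim_small$z_x1[1, ]), 0.5)
})

test_that("scaling both matrices scales scores and fixes correlations", {
  c0 <- 3.7
  f1 <- paca(sim_small$x, sim_small$y, k = 2, k1 = 1)
  f2 <- paca(c0 * sim_small$x, c0 * sim_small$y, k = 2, k1 = 1)
  expect_equal(f1$cca$cor, f2$cca$cor, tolerance = 1e-8)
  expect_equal(f2$scores, c0 * f1$scores, tolerance = 1e-8)
})

test_that("permuting case columns permutes scores; control order is irrelevant", {
  set.seed(55)
  pc <- sample(ncol(sim_small$x))
  p0 <- sample(ncol(sim_small$y))
  f <- paca(sim_small$x, sim_small$y, k = 2, k1 = 1)
  f_case <- paca(sim_small$x[, pc], sim_small$y, k = 2, k1 = 1)
  expect_equal(f_case$scores, f$scores[pc, , drop = FALSE],
               tolerance = 1e-10)
  f_ctrl <- paca(sim_small$x, sim_small$y[, p0], k = 2, k1 = 1)
  expect_equal(f_ctrl$scores, f$scores, tolerance = 1e-10)
})

test_that("mismatched feature sets are reported with the symmetric difference", {
  x <- sim_small$x
  y <- sim_small$y
  rownames(y)[1] <- "other_probe"
  expect_error(paca(x, y, k = 1), class = "paca_error_features")
  expect_error(paca(x, y, k = 1), "other_probe")
  y2 <- sim_small$y[rev(rownames(sim_small$y)), ]
  expect_error(paca(x, y2, k = 1), "align_features")
})

test_that("projection reproduces training scores and respects feature order", {
  fit <- paca(sim_small$x, sim_small$y, k = 2, k1 = 2)
  expect_lt(max(abs(predict(fit, sim_small$x) - fit$scores)), 1e-12)
  perm <- sample(nrow(sim_small$x))
  expect_equal(predict(fit, sim_small$x[perm, ]), fit$scores,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("projection validates and trims the feature set of new data", {
  fit <- paca(sim_small$x, sim_small$y, k = 1, k1 = 1)
  expect_error(predict(fit, sim_small$x[-1, ]), "missing")
  extra <- rbind(sim_small$x, extra_probe = rnorm(ncol(sim_small$x)))
  expect_warning(s <- predict(fit, extra), "dropping 1")
  expect_equal(s, fit$scores, tolerance = 1e-12)
})

test_that("a fitted model transfers to a replication cohort", {
  sim <- simulate_paca_data(seed = 301)
  rep <- simulate_replication(sim, seed = 302)
  fit <- paca(sim$x, sim$y, k = 3, k1 = 1)
  proj <- predict(fit, rep$x)
  expect_gt(abs_cor(proj[, 1], rep$z_x1[1, ]), 0.8)
})

test_that("per-feature pre-centering is recorded and replayed by predict", {
  fit <- paca(sim_small$x, sim_small$y, k = 1, k1 = 1,
              center_features = TRUE)
  expect_true(fit$center_features)
  expect_lt(max(abs(predict(fit, sim_small$x) - fit$scores)), 1e-12)
})
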