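test_that("the 80/20 split is seeded, disjoint and exhaustive", {
  sp <- splitDataset(89)
  expect_length(sp@test_indices, 18L)
  expect_length(sp@train_indices, 71L)
  expect_identical(splitDataset(89)@test_indices, sp@test_indices)
  expect_false(identical(splitDataset(89, seed = 21)@test_indices,
                         sp@test_indices))
  for (n in withr::with_seed(1, sample(10:100, 8))) {
    s <- splitDataset(n)
    expect_length(intersect(s@train_indices, s@test_indices), 0L)
    expect_setequal(c(s@train_indices, s@test_indices), seq_len(n))
    expect_length(s@test_indices, round(0.2 * n))
  }
  expect_error(splitDataset(89, test_fraction = 1.2), "test_fraction")
  expect_error(splitDataset(4), "at least 5")
})

test_that("NIPALS satisfies the bilinear decomposition identities", {
  d <- makeToyDataset(n = 20, K = 10, seed = 31)
  m <- fitPLSR(d$X, d$y, n_lvs = 4L)
  ## score orthogonality
  G <- crossprod(m@scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
  ## X = T P' + E and y = T q + f on centred data
  Xc <- sweep(d$X, 2, m@x_mean)
  expect_equal(Xc, m@scores %*% t(m@x_loadings) + m@residuals_x)
  expect_equal(d$y - m@y_mean,
               drop(m@scores %*% m@y_loadings) + m@residuals_y)
  ## unit-norm weights; first weight is the normalised X'y
  expect_equal(colSums(m@weights^2), rep(1, 4))
  w1 <- drop(crossprod(Xc, d$y - m@y_mean))
  expect_equal(m@weights[, 1], w1 / sqrt(sum(w1^2)))
})

test_that("beta and score prediction pathways agree", {
  d <- makeToyDataset(n = 15, K = 8, n_informative = 4, seed = 32)
  m <- fitPLSR(d$X, d$y, n_lvs = 3L)
  Xn <- matrix(rnorm(40), 5, 8)
  expect_equal(predict(m, Xn), predict(m, Xn, pathway = "scores"),
               tolerance = 1e-10)
  ## training predictions reproduce the stored fitted values
  expect_equal(predict(m, d$X), m@fitted)
  ## the mean spectrum predicts the mean response
  expect_equal(predict(m, rbind(m@x_mean)), m@y_mean)
  expect_error(predict(m, Xn[, 1:5]), "bands")
})

test_that("an exactly linear response is fitted exactly at full rank", {
  withr::with_seed(33, {
    X <- matrix(rnorm(60), 20, 3)
    y <- drop(X %*% c(1, -2, 0.5)) + 4
  })
  m <- fitPLSR(X, y, n_lvs = 3L)
  expect_lt(max(abs(m@residuals_y)), 1e-10)
  ## PLSR at J = rank equals the OLS fit
  ols <- lm(y ~ X)
  expect_equal(m@coefficients, unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("NIPALS predictions match the SIMPLS reference implementation", {
  for (seed in 1:10) {
    d <- makeToyDataset(n = 20, K = 10, n_informative = 5, seed = seed)
    Xn <- withr::with_seed(seed + 1000, matrix(rnorm(50), 5, 10))
    for (J in c(1L, 3L, 5L)) {
      m <- fitPLSR(d$X, d$y, n_lvs = J)
      o <- simplsOracle(d$X, d$y, J)
      expect_equal(predict(m, Xn), o$predict(Xn), tolerance = 1e-8,
                   label = sprintf("seed %d J %d", seed, J))
    }
  }
})

test_that("NIPALS predictions match an independent library implementation", {
  skip_if_not_installed("mixOmics")
  d <- makeToyDataset(n = 20, K = 10, seed = 35)
  colnames(d$X) <- paste0("b", 1:10)
  Xn <- withr::with_seed(77, matrix(rnorm(50), 5, 10,
                                    dimnames = list(NULL, colnames(d$X))))
  m <- fitPLSR(d$X, d$y, n_lvs = 3L)
  ref <- mixOmics::pls(d$X, d$y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  p_ref <- predict(ref, Xn)$predict[, 1, 3]
  expect_equal(unname(predict(m, Xn)), unname(p_ref), tolerance = 1e-8)
})

test_that("leave-one-out CV recovers the latent dimension", {
  ## noiseless rank-2 response: RMSECV must bottom out at J = 2
  withr::with_seed(36, {
    Tm <- matrix(rnorm(60), 30, 2)
    L <- matrix(rnorm(16), 2, 8)
    X <- Tm %*% L
    y <- drop(Tm %*% c(2, -1))
  })
  m <- selectNumLVs(X, y, max_lvs = 6L)
  expect_equal(m@n_lvs, 2L)
  expect_length(m@rmsecv, 6L)
  expect_true(all(m@rmsecv[m@n_lvs] <= m@rmsecv))
})

test_that("degenerate inputs are rejected or truncated", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fitPLSR(X, rep(1, 10), n_lvs = 2), "zero variance")
  expect_error(fitPLSR(X, rnorm(10), n_lvs = 11), "n_lvs")
  ## rank-1 X cannot yield more than one component
  X1 <- outer(rnorm(10), rnorm(4))
  y <- drop(X1[, 1]) + rnorm(10, 0, 1e-6)
  expect_warning(m <- fitPLSR(X1, y, n_lvs = 3), "stopped at")
  expect_lte(m@n_lvs, 2L)
})

test_that("LASSO at alpha = 0 is least squares (minimum-norm if needed)", {
  d <- makeToyDataset(n = 30, K = 5, n_informative = 3, seed = 37)
  m0 <- fitLasso(d$X, d$y, alpha = 0)
  ols <- lm(d$y ~ d$X)
  expect_equal(m0@coefficients, unname(coef(ols)[-1]), tolerance = 1e-8)
  ## rank-deficient: coefficients must be the minimum-norm LS solution
  Xr <- cbind(d$X, d$X[, 1] + d$X[, 2])
  mr <- fitLasso(Xr, d$y, alpha = 0)
  Xc <- sweep(Xr, 2, colMeans(Xr))
  sv <- svd(Xc)
  keep <- sv$d > 1e-10 * sv$d[1]
  pinv_beta <- drop(sv$v[, keep] %*%
                      (crossprod(sv$u[, keep], d$y - mean(d$y)) /
                         sv$d[keep]))
  expect_equal(mr@coefficients, pinv_beta, tolerance = 1e-8)
})

test_that("LASSO matches the soft-threshold closed form on orthonormal designs", {
  withr::with_seed(38, {
    Q <- qr.Q(qr(matrix(rnorm(400), 40, 10)))
    beta_true <- c(3, -2, 1.5, rep(0, 7))
    y <- drop(Q %*% beta_true) + rnorm(40, 0, 0.1)
  })
  Qc <- sweep(Q, 2, colMeans(Q))
  ## re-orthonormalise after centring so the closed form is exact
  Qc <- qr.Q(qr(Qc))
  yc <- y - mean(y)
  z <- drop(crossprod(Qc, yc))
  for (alpha in c(0.5, 1, 2)) {
    m <- fitLasso(Qc, yc, alpha = alpha)
    soft <- sign(z) * pmax(abs(z) - alpha / 2, 0)
    expect_equal(m@coefficients, soft, tolerance = 1e-8)
  }
})

test_that("the penalty that zeroes every coefficient is 2 max |X'y|", {
  d <- makeToyDataset(n = 25, K = 12, seed = 39)
  Xc <- sweep(d$X, 2, colMeans(d$X))
  alpha_max <- 2 * max(abs(crossprod(Xc, d$y - mean(d$y))))
  expect_equal(fitLasso(d$X, d$y, alpha = alpha_max * 1.0001)@coefficients,
               rep(0, 12))
  expect_gt(length(fitLasso(d$X, d$y,
                            alpha = alpha_max * 0.9)@active_set), 0L)
})

test_that("KKT conditions hold at convergence on random problems", {
  for (seed in 40:44) {
    d <- makeToyDataset(n = 25, K = 15, seed = seed)
    Xc <- sweep(d$X, 2, colMeans(d$X))
    yc <- d$y - mean(d$y)
    alpha <- 0.3 * 2 * max(abs(crossprod(Xc, yc)))
    m <- fitLasso(d$X, d$y, alpha = alpha)
    g <- drop(crossprod(Xc, yc - Xc %*% m@coefficients))
    act <- m@active_set
    if (length(act))
      expect_lt(max(abs(g[act] - (alpha / 2) *
                          sign(m@coefficients[act]))), 1e-6)
    expect_lt(max(abs(g[-act])), alpha / 2 + 1e-6)
  }
})

test_that("LASSO agrees with glmnet under the penalty mapping", {
  skip_if_not_installed("glmnet")
  d <- makeToyDataset(n = 30, K = 12, seed = 45)
  N <- nrow(d$X)
  alpha <- 0.2 * 2 * max(abs(crossprod(
    sweep(d$X, 2, colMeans(d$X)), d$y - mean(d$y))))
  m <- fitLasso(d$X, d$y, alpha = alpha)
  g <- glmnet::glmnet(d$X, d$y, lambda = alpha / (2 * N),
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(m@coefficients, as.numeric(g$beta), tolerance = 1e-5)
})

test_that("models are invariant to sample order", {
  d <- makeToyDataset(n = 24, K = 10, seed = 46)
  perm <- withr::with_seed(47, sample(24))
  mp <- fitPLSR(d$X, d$y, 3L)
  mp2 <- fitPLSR(d$X[perm, ], d$y[perm], 3L)
  expect_equal(mp@coefficients, mp2@coefficients, tolerance = 1e-10)
  alpha <- 1
  ml <- fitLasso(d$X, d$y, alpha)
  ml2 <- fitLasso(d$X[perm, ], d$y[perm], alpha)
  expect_equal(ml@coefficients, ml2@coefficients, tolerance = 1e-6)
})

test_that("alpha selection by LOO CV behaves as specified", {
  d <- makeToyDataset(n = 20, K = 8, n_informative = 3, seed = 48)
  one <- selectAlpha(d$X, d$y, alpha_grid = 0.7)
  expect_equal(one@alpha, 0.7)
  m <- selectAlpha(d$X, d$y, n_alpha = 12L)
  expect_length(m@cv_rmse, 12L)
  expect_length(m@alpha_grid, 12L)
  expect_equal(m@alpha, m@alpha_grid[which.min(m@cv_rmse)])
})

test_that("alpha selection recovers a sparse truth with few spurious picks", {
  ## well-separated sparse signal at SNR 20: the chosen model keeps every
  ## truly active variable and at most 2 spurious ones
  withr::with_seed(49, {
    X <- qr.Q(qr(matrix(rnorm(60 * 12), 60, 12))) * sqrt(60)
    beta <- c(1, -1, 0.8, rep(0, 9))
    signal <- drop(X %*% beta)
    y <- signal + rnorm(60, 0, sd(signal) / 20)
  })
  m <- selectAlpha(X, y)
  expect_true(all(1:3 %in% m@active_set))
  expect_lte(length(setdiff(m@active_set, 1:3)), 2L)
})

test_that("non-convergence raises an informative error", {
  d <- makeToyDataset(n = 20, K = 30, seed = 50)
  expect_error(fitLasso(d$X, d$y, alpha = 1e-9, max_iter = 3L,
                        kkt_late_tol = 0),
               "did not converge.*duality gap")
})
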