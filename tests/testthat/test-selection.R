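fitToy <- function(seed = 1, n = 20, K = 12, J = 3) {
  d <- makeToyDataset(n = n, K = K, n_informative = min(K, 6),
                      seed = seed)
  fitPLSR(d$X, d$y, n_lvs = J)
}

test_that("beta selection thresholds at the coefficient SD", {
  m <- fitToy(seed = 61, K = 4, J = 2)
  beta <- c(3, -3, 0.1, -0.1)
  m@coefficients <- beta
  sel <- betaSelect(m)
  ## population SD of (3,-3,0.1,-0.1) is ~2.12; sample SD ~2.45; either
  ## way exactly the two large-magnitude bands survive
  expect_equal(sel@retained_indices, c(1L, 2L))
  expect_equal(sel@threshold, sqrt(mean((beta - mean(beta))^2)))
  expect_equal(betaSelect(m, sd_type = "sample")@retained_indices,
               c(1L, 2L))
  expect_equal(betaSelect(m, sd_type = "sample")@threshold, sd(beta))
  ## sign flip leaves retention unchanged
  m@coefficients <- -beta
  expect_equal(betaSelect(m)@retained_indices, sel@retained_indices)
})

test_that("boundary coefficients on the SD threshold are retained", {
  m <- fitToy(seed = 62, K = 4, J = 2)
  ## equal magnitudes, sign-balanced: |beta_j| equals the SD for all j
  m@coefficients <- c(1, -1, 1, -1)
  expect_equal(betaSelect(m)@retained_indices, 1:4)
})

test_that("VIP scores satisfy the mean-square identity", {
  for (seed in 1:12) {
    m <- fitToy(seed = seed, J = 1 + seed %% 4)
    v <- vipScores(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-10,
                 label = paste("seed", seed))
  }
})

test_that("single-component VIP collapses to scaled weights", {
  m <- fitToy(seed = 63, J = 1)
  K <- length(m@coefficients)
  expect_equal(vipScores(m),
               sqrt(K) * abs(m@weights[, 1]) /
                 sqrt(sum(m@weights[, 1]^2)))
})

test_that("VIP scores match a literal transcription of the formula", {
  for (seed in c(64, 65)) {
    m <- fitToy(seed = seed, J = 4)
    expect_equal(vipScores(m), vipOracle(m), tolerance = 1e-12)
  }
})

test_that("VIP selection respects thresholds and is monotone", {
  m <- fitToy(seed = 66, J = 3)
  all_in <- vipSelect(m, threshold = 0)
  expect_equal(all_in@retained_indices, seq_along(m@coefficients))
  ## ViP mean square = 1 guarantees non-empty retention at threshold 1
  at1 <- vipSelect(m)
  expect_gte(length(at1@retained_indices), 1L)
  prev <- all_in@retained_indices
  for (thr in c(0.5, 1, 1.3)) {
    cur <- vipSelect(m, threshold = thr)@retained_indices
    expect_true(all(cur %in% prev), label = paste("threshold", thr))
    prev <- cur
  }
  expect_error(vipSelect(m, threshold = 100), "every band")
})

test_that("refit on an identity selection reproduces the parent metrics", {
  d <- makeToyDataset(n = 30, K = 10, n_informative = 6, seed = 67)
  tr <- 1:22; te <- 23:30
  parent <- selectNumLVs(d$X[tr, ], d$y[tr], max_lvs = 6L)
  sel <- vipSelect(parent, threshold = 0)  # retains every band
  out <- refitOnSelection(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te], sel,
                          max_lvs = 6L)
  direct <- evaluateModel(parent, d$X[tr, ], d$y[tr], d$X[te, ], d$y[te])
  expect_equal(out$report@r2_test, direct@r2_test)
  expect_equal(out$report@rmse_train, direct@rmse_train)
  ## a reduced band set shrinks the refitted coefficient vector
  sel2 <- betaSelect(parent)
  out2 <- refitOnSelection(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te], sel2,
                           max_lvs = 6L)
  expect_equal(length(out2$model@coefficients),
               length(sel2@retained_indices))
  expect_lt(length(out2$model@coefficients), 10L)
})

test_that("both selection methods recover planted informative bands", {
  ## 10 informative bands out of 60 at SNR 20: each method must keep at
  ## least 8 of the 10 (and the grid of the two methods is deterministic)
  d <- makeToyDataset(n = 60, K = 60, n_informative = 10, snr = 20,
                      seed = 68)
  m <- selectNumLVs(d$X, d$y, max_lvs = 12L)
  for (sel in list(betaSelect(m), vipSelect(m))) {
    hits <- length(intersect(sel@retained_indices, d$informative))
    expect_gte(hits, 8L)
  }
  ## determinism given the parent model
  expect_identical(betaSelect(m)@retained_indices,
                   betaSelect(m)@retained_indices)
})

test_that("selection results carry wavelengths and survive serialisation", {
  sim <- simulateGingerDataset(simulationParams(
    n_samples = 16, n_bands = 40, cube_rows = 4, cube_cols = 4, seed = 3))
  m <- selectNumLVs(sim, max_lvs = 5L)
  sel <- vipSelect(m)
  expect_equal(sel@retained_wavelengths,
               wavelengths(sim)[sel@retained_indices])
  expect_equal(sel@n_bands, 40L)
})
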