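## Independent oracles used across the suite. These deliberately take the
## slow, literal route (loops, per-window polynomial fits, a different PLS
## algorithm) so they share no code path with the implementation they
## check.

## SIMPLS (de Jong 1993) for a single response. For one y, SIMPLS and
## NIPALS PLS1 give identical predictions, but the algorithm (basis
## deflation of the cross-product vector) is entirely different.
simplsOracle <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  K <- ncol(Xc)
  R <- V <- matrix(0, K, ncomp)
  q <- numeric(ncomp)
  s <- drop(crossprod(Xc, yc))
  for (a in seq_len(ncomp)) {
    r <- s
    t <- drop(Xc %*% r)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {
      R <- R[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      break
    }
    t <- t / nt
    r <- r / nt
    p <- drop(crossprod(Xc, t))
    q[a] <- sum(yc * t)
    v <- p
    if (a > 1) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - drop(Va %*% crossprod(Va, p))
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    R[, a] <- r
    V[, a] <- v
  }
  beta <- drop(R %*% q)
  list(beta = beta, x_mean = xm, y_mean = ym,
       predict = function(Xn) drop(sweep(as.matrix(Xn), 2, xm) %*% beta) + ym)
}

## literal loop transcription of the single-response VIP formula
vipOracle <- function(model) {
  W <- model@weights
  Tm <- model@scores
  q <- model@y_loadings
  K <- nrow(W)
  A <- ncol(W)
  ssy <- vapply(seq_len(A), function(a) q[a]^2 * sum(Tm[, a]^2),
                numeric(1))
  out <- numeric(K)
  for (j in seq_len(K)) {
    acc <- 0
    for (a in seq_len(A))
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    out[j] <- sqrt(K * acc / sum(ssy))
  }
  out
}

## per-window local polynomial least-squares derivative (Savitzky-Golay by
## first principles), including the one-sided edge fits
sgOracle <- function(x, polyorder, window, deriv, spacing = 1) {
  K <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(K)
  for (i in seq_len(K)) {
    if (i <= h) {
      idx <- 1:window; at <- i
    } else if (i > K - h) {
      idx <- (K - window + 1L):K; at <- i
    } else {
      idx <- (i - h):(i + h); at <- i
    }
    z <- (idx - at) * spacing
    fit <- lm.fit(outer(z, 0:polyorder, `^`), x[idx])
    out[i] <- fit$coefficients[deriv + 1L] * factorial(deriv)
  }
  out
}

## brute-force truncated moving average
meanFilterOracle <- function(x, width) {
  K <- length(x)
  h <- (width - 1L) %/% 2L
  vapply(seq_len(K), function(i)
    mean(x[max(1, i - h):min(K, i + h)]), numeric(1))
}

## hand-computed 5-point toy set for the evaluation metrics: the sums were
## derived by hand arithmetic before the implementation existed.
## errors: 0.2 -0.1 0.3 -0.2 0.1 -> SSE 0.19; Sxx 10; Sxy 9.70;
## predicted mean 3.06, squared deviations sum 9.572.
toyMetrics <- list(
  y_m = c(1, 2, 3, 4, 5),
  y_p = c(1.2, 1.9, 3.3, 3.8, 5.1),
  r2 = 1 - 0.19 / 10,            # 0.981
  rmse = sqrt(0.19 / 5),         # 0.1949359
  sd_pred = sqrt(9.572 / 4),     # 1.5469324
  rpd = sqrt(9.572 / 4) / sqrt(0.19 / 5),  # 7.935600
  slope = 9.70 / 10,             # 0.97
  lod = 3 * sqrt(0.19 / 5) / 0.97)         # 0.6028946

## small random spectra fixture (samples x bands) with a planted linear
## response; used by regression/selection property tests
makeToyDataset <- function(n = 24, K = 40, n_informative = 10,
                           snr = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * K), n, K)
    info <- sort(sample.int(K, n_informative))
    beta <- numeric(K)
    beta[info] <- runif(n_informative, 0.5, 1.5) *
      sample(c(-1, 1), n_informative, replace = TRUE)
    signal <- drop(X %*% beta)
    noise <- rnorm(n, 0, sd(signal) / snr)
    list(X = X, y = signal + noise, beta = beta, informative = info)
  })
}

## small HyperCube fixture
makeToyCube <- function(rows = 4, cols = 5, bands = 6, seed = 1,
                        scale = "reflectance") {
  withr::with_seed(seed, HyperCube(
    array(runif(rows * cols * bands), c(rows, cols, bands)),
    wavelengths = seq(400, 1000, length.out = bands), scale = scale))
}
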