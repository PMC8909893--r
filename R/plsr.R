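## NIPALS partial least squares regression, single response (PLS1).
##
## Per component: weight w = X'y / ||X'y||, score t = Xw, x-loading
## p = X't / t't, y-loading q = y't / t't, then deflation X <- X - t p',
## y <- y - t q. The regression vector on centred data is
## beta = W (P'W)^-1 q, and prediction through beta coincides with the
## score pathway.

.nipals <- function(Xc, yc, n_lvs) {
  N <- nrow(Xc); K <- ncol(Xc)
  W <- P <- matrix(0, K, n_lvs)
  Tm <- matrix(0, N, n_lvs)
  q <- numeric(n_lvs)
  achieved <- 0L
  for (a in seq_len(n_lvs)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (sqrt(tt) < 1e-12) break
    p <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
    achieved <- a
  }
  list(W = W[, seq_len(achieved), drop = FALSE],
       P = P[, seq_len(achieved), drop = FALSE],
       T = Tm[, seq_len(achieved), drop = FALSE],
       q = q[seq_len(achieved)],
       E = Xc, f = yc, achieved = achieved)
}

## beta for the first n_comp components of a NIPALS state
.nipalsBeta <- function(st, n_comp = st$achieved) {
  j <- seq_len(n_comp)
  W <- st$W[, j, drop = FALSE]
  P <- st$P[, j, drop = FALSE]
  drop(W %*% solve(crossprod(P, W), st$q[j]))
}

.asXy <- function(x, y) {
  if (is(x, "SpectralDataset")) {
    list(X = spectraMatrix(x), y = if (is.null(y)) ratios(x) else y,
         wl = wavelengths(x))
  } else {
    X <- stopIfNotMatrix(x)
    list(X = X, y = y, wl = numeric(ncol(X)))
  }
}

#' Fit a PLSR model by NIPALS
#'
#' Fits single-response partial least squares regression with `n_lvs`
#' latent variables on internally mean-centred data (centring constants are
#' stored; no variance scaling by default, matching the package's symmetric
#' treatment of PLSR and LASSO).
#'
#' If a component's score norm collapses below 1e-12 the decomposition
#' stops early with a warning and the achieved number of components is
#' returned.
#'
#' @param x samples x bands matrix or [SpectralDataset-class].
#' @param y response vector (gingerol:shogaol ratio); taken from the
#'   dataset when `x` is a `SpectralDataset`.
#' @param n_lvs number of latent variables J, at most `min(N - 1, K)`.
#' @return A [PLSRModel-class].
#' @seealso [selectNumLVs()], [predict,PLSRModel-method]
#' @export
fitPLSR <- function(x, y = NULL, n_lvs = 2L) {
  d <- .asXy(x, y)
  X <- d$X; y <- d$y
  n_lvs <- as.integer(n_lvs)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (var(y) == 0) stop("response has zero variance")
  if (n_lvs < 1L || n_lvs > min(nrow(X) - 1L, ncol(X)))
    stop("n_lvs must lie in [1, min(N - 1, K)]")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  st <- .nipals(sweep(X, 2, x_mean), y - y_mean, n_lvs)
  if (st$achieved == 0L) stop("no PLS component could be extracted")
  if (st$achieved < n_lvs)
    warning(sprintf("degenerate component: stopped at %d of %d LVs",
                    st$achieved, n_lvs))
  beta <- .nipalsBeta(st)
  new("PLSRModel", n_lvs = st$achieved, weights = st$W, scores = st$T,
      x_loadings = st$P, y_loadings = st$q, coefficients = beta,
      x_mean = x_mean, y_mean = y_mean, residuals_x = st$E,
      residuals_y = st$f,
      fitted = drop(sweep(X, 2, x_mean) %*% beta) + y_mean,
      rmsecv = numeric(0), wavelengths = d$wl)
}

#' Choose the number of latent variables by leave-one-out CV
#'
#' For each candidate J from 1 to `max_lvs`, every training sample is held
#' out in turn, the model is refitted on the remainder, and the held-out
#' sample predicted; J* minimises the cross-validated RMSE (ties go to the
#' smallest J, the more parsimonious model). The returned model is refitted
#' on the full training set at J* and carries the RMSECV curve.
#'
#' @inheritParams fitPLSR
#' @param max_lvs largest candidate J (default 20, capped at
#'   `min(N - 2, K)`).
#' @return A [PLSRModel-class] with the `rmsecv` slot filled.
#' @export
selectNumLVs <- function(x, y = NULL, max_lvs = 20L) {
  d <- .asXy(x, y)
  X <- d$X; y <- d$y
  N <- nrow(X)
  max_lvs <- min(as.integer(max_lvs), N - 2L, ncol(X))
  if (max_lvs < 1L) stop("too few samples for cross-validation")
  press <- matrix(NA_real_, N, max_lvs)
  for (i in seq_len(N)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    st <- .nipals(sweep(Xi, 2, xm), yi - ym, max_lvs)
    xc <- X[i, ] - xm
    for (J in seq_len(st$achieved))
      press[i, J] <- (sum(xc * .nipalsBeta(st, J)) + ym - y[i])^2
    if (st$achieved < max_lvs)   # degenerate folds: reuse the last beta
      press[i, (st$achieved + 1L):max_lvs] <- press[i, st$achieved]
  }
  rmsecv <- sqrt(colMeans(press))
  j_star <- which.min(rmsecv)
  fit <- fitPLSR(X, y, n_lvs = j_star)
  fit@rmsecv <- rmsecv
  fit@wavelengths <- d$wl
  fit
}

#' Predict from a PLSR model
#'
#' `y_hat = (X_new - x_mean) beta + y_mean`. With `pathway = "scores"` the
#' new samples are instead projected component-wise (with deflation) and
#' predicted through the score/y-loading route; the two pathways agree to
#' machine tolerance.
#'
#' @param object a [PLSRModel-class].
#' @param newdata samples x bands matrix or [SpectralDataset-class] with
#'   the same band count (and pre-treatment) as the training data.
#' @param pathway `"beta"` (default) or `"scores"`.
#' @param ... unused.
#' @return numeric vector of predicted ratios.
#' @export
setMethod("predict", "PLSRModel",
          function(object, newdata, pathway = c("beta", "scores"), ...) {
  pathway <- match.arg(pathway)
  X <- if (is(newdata, "SpectralDataset")) spectraMatrix(newdata)
       else stopIfNotMatrix(newdata)
  if (ncol(X) != length(object@coefficients))
    stop(sprintf("newdata has %d bands but the model was fitted on %d",
                 ncol(X), length(object@coefficients)))
  Xc <- sweep(X, 2, object@x_mean)
  if (pathway == "beta")
    return(drop(Xc %*% object@coefficients) + object@y_mean)
  yhat <- rep(object@y_mean, nrow(X))
  for (a in seq_len(object@n_lvs)) {
    t_new <- drop(Xc %*% object@weights[, a])
    yhat <- yhat + t_new * object@y_loadings[a]
    Xc <- Xc - tcrossprod(t_new, object@x_loadings[, a])
  }
  yhat
})
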