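## Wavelength selection from a fitted PLSR model: beta-coefficient
## SD-thresholding and VIP >= 1. Selection uses the training fit only; the
## test split never influences retention.

#' Beta-coefficient wavelength selection
#'
#' Bands whose absolute PLSR regression coefficient is below the standard
#' deviation of all coefficients are discarded; bands on the boundary
#' (score equal to the threshold) are retained. Large positive or negative
#' coefficients mark wavelengths that drive the prediction.
#'
#' @param model a fitted [PLSRModel-class].
#' @param sd_type `"population"` (1/K denominator, default) or `"sample"`
#'   (1/(K-1)); the retained set rarely differs.
#' @return A [SelectionResult-class].
#' @seealso [vipSelect()], [refitOnSelection()]
#' @export
betaSelect <- function(model, sd_type = c("population", "sample")) {
  stopifnot(is(model, "PLSRModel"))
  sd_type <- match.arg(sd_type)
  beta <- model@coefficients
  thr <- if (sd_type == "population") sdPop(beta) else sd(beta)
  keep <- which(abs(beta) >= thr)
  if (!length(keep))
    stop("beta selection discarded every band; review the threshold ",
         "(SD of the coefficients) against the coefficient profile")
  wl <- model@wavelengths
  new("SelectionResult", method = "beta_coefficient", scores = abs(beta),
      threshold = thr, retained_indices = as.integer(keep),
      retained_wavelengths = if (length(wl)) wl[keep] else numeric(length(keep)),
      n_bands = length(beta))
}

#' VIP scores of a PLSR model
#'
#' Variable importance in projection for single-response PLS:
#' \deqn{VIP_j = \sqrt{K \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where `SSY_a = q_a^2 t_a' t_a` is the response variance explained by
#' component a. The scores are mean-square normalised:
#' `mean(VIP^2) == 1`, which is what makes 1 the conventional retention
#' threshold.
#'
#' @param model a fitted [PLSRModel-class].
#' @return numeric vector of VIP scores, one per band.
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "PLSRModel"))
  W <- model@weights
  ssy <- model@y_loadings^2 * colSums(model@scores^2)
  if (sum(ssy) <= 0) stop("model explains no response variance")
  W2 <- sweep(W^2, 2, colSums(W^2), "/")
  sqrt(nrow(W) * drop(W2 %*% ssy) / sum(ssy))
}

#' VIP wavelength selection
#'
#' Retains bands with VIP score at least `threshold` (default 1). By the
#' mean-square identity of the VIP formula at least one band always meets
#' the default threshold.
#'
#' @param model a fitted [PLSRModel-class].
#' @param threshold retention cutoff (default 1).
#' @return A [SelectionResult-class].
#' @export
vipSelect <- function(model, threshold = 1) {
  scores <- vipScores(model)
  keep <- which(scores >= threshold)
  if (!length(keep))
    stop("VIP selection discarded every band at threshold ", threshold)
  wl <- model@wavelengths
  new("SelectionResult", method = "vip", scores = scores,
      threshold = threshold, retained_indices = as.integer(keep),
      retained_wavelengths = if (length(wl)) wl[keep] else numeric(length(keep)),
      n_bands = length(scores))
}

#' Refit PLSR on the retained wavelengths
#'
#' Subsets both splits to the retained bands, re-selects the
#' latent-variable count by leave-one-out cross-validation on the reduced
#' training matrix, refits, and evaluates.
#'
#' @param x_train,y_train training spectra (samples x bands) and response.
#' @param x_test,y_test test spectra and response.
#' @param selection a [SelectionResult-class].
#' @param max_lvs passed to [selectNumLVs()].
#' @param treatment provenance tag for the report.
#' @return list with the refitted `model` ([PLSRModel-class]) and its
#'   `report` ([EvaluationReport-class]).
#' @export
refitOnSelection <- function(x_train, y_train = NULL, x_test,
                             y_test = NULL, selection, max_lvs = 20L,
                             treatment = "raw") {
  stopifnot(is(selection, "SelectionResult"))
  dtr <- .asXy(x_train, y_train)
  dte <- .asXy(x_test, y_test)
  j <- selection@retained_indices
  model <- selectNumLVs(dtr$X[, j, drop = FALSE], dtr$y,
                        max_lvs = max_lvs)
  model@wavelengths <- selection@retained_wavelengths
  report <- evaluateModel(model, dtr$X[, j, drop = FALSE], dtr$y,
                          dte$X[, j, drop = FALSE], dte$y,
                          treatment = treatment,
                          selection = selection@method)
  list(model = model, report = report)
}
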