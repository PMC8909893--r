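## Model evaluation metrics: R2, RMSE, RPD per split, and the limit of
## detection from the calibration (training) split.

#' Coefficient of determination
#'
#' `1 - sum((y_p - y_m)^2) / sum((y_m - mean(y_m))^2)`, the standard form.
#' `printed_form = TRUE` switches the denominator to
#' `sum((y_p - mean(y_m))^2)`, a nonstandard variant that can exceed 1 and
#' is provided for compatibility only.
#'
#' @param measured reference (measured) ratios.
#' @param predicted model predictions, same length.
#' @param printed_form use the compatibility denominator (default FALSE).
#' @return numeric scalar.
#' @export
rSquared <- function(measured, predicted, printed_form = FALSE) {
  stopifnot(length(measured) == length(predicted))
  if (var(measured) == 0) stop("measured values have zero variance")
  den <- if (printed_form) sum((predicted - mean(measured))^2)
         else sum((measured - mean(measured))^2)
  1 - sum((predicted - measured)^2) / den
}

#' Root mean square error
#'
#' `sqrt(mean((y_p - y_m)^2))` — denominator m, not m - 1.
#'
#' @inheritParams rSquared
#' @return numeric scalar (response units).
#' @export
rmse <- function(measured, predicted) {
  stopifnot(length(measured) == length(predicted))
  sqrt(mean((predicted - measured)^2))
}

#' Ratio of performance to deviation
#'
#' `SD / RMSE` computed per split. As printed in the source model, the SD
#' is that of the *predicted* values (sample SD, m - 1 denominator);
#' `sd_of = "measured"` gives the conventional variant. Models with RPD of
#' at least 1.4 are flagged "good" downstream.
#'
#' @inheritParams rSquared
#' @param sd_of `"predicted"` (default, as defined here) or `"measured"`.
#' @return numeric scalar.
#' @export
rpd <- function(measured, predicted, sd_of = c("predicted", "measured")) {
  sd_of <- match.arg(sd_of)
  e <- rmse(measured, predicted)
  if (e == 0) stop("RMSE is zero; RPD is infinite")
  sd(if (sd_of == "predicted") predicted else measured) / e
}

#' OLS calibration slope
#'
#' Slope of the ordinary least-squares line of predicted on measured
#' values, the "slope of the calibration" used by the limit of detection.
#'
#' @inheritParams rSquared
#' @return numeric scalar.
#' @export
calibrationSlope <- function(measured, predicted) {
  mc <- measured - mean(measured)
  sum(mc * predicted) / sum(mc^2)
}

#' Limit of detection
#'
#' `3 * RMSE_cal / slope_cal`, with both quantities taken from the
#' calibration (training) split: the smallest gingerol:shogaol ratio
#' distinguishable from the model's noise floor.
#'
#' @param rmse_cal training-set RMSE.
#' @param slope_cal training-set calibration slope
#'   ([calibrationSlope()]).
#' @return numeric scalar (ratio units).
#' @export
limitOfDetection <- function(rmse_cal, slope_cal) {
  if (slope_cal == 0) stop("calibration slope is zero")
  3 * rmse_cal / slope_cal
}

#' Evaluate a fitted model on both splits
#'
#' Computes R2, RMSE and RPD for the training and testing splits, the
#' limit of detection from the training split, and the quality flag
#' ("good" when the testing RPD is at least 1.4).
#'
#' @param model a [PLSRModel-class] or [LassoModel-class].
#' @param x_train,y_train,x_test,y_test the two splits (matrices or
#'   [SpectralDataset-class]s, responses taken from the dataset when
#'   omitted).
#' @param treatment,selection provenance tags for the report row.
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(model, x_train, y_train = NULL, x_test,
                          y_test = NULL, treatment = "raw",
                          selection = "none") {
  dtr <- .asXy(x_train, y_train)
  dte <- .asXy(x_test, y_test)
  p_tr <- predict(model, dtr$X)
  p_te <- predict(model, dte$X)
  rmse_tr <- rmse(dtr$y, p_tr)
  ## a perfect fit has infinite RPD rather than being unreportable
  rpdSafe <- function(m, p) if (rmse(m, p) == 0) Inf else rpd(m, p)
  rpd_te <- rpdSafe(dte$y, p_te)
  is_plsr <- is(model, "PLSRModel")
  new("EvaluationReport",
      r2_train = rSquared(dtr$y, p_tr), r2_test = rSquared(dte$y, p_te),
      rmse_train = rmse_tr, rmse_test = rmse(dte$y, p_te),
      rpd_train = rpdSafe(dtr$y, p_tr), rpd_test = rpd_te,
      lod = limitOfDetection(rmse_tr, calibrationSlope(dtr$y, p_tr)),
      quality = if (rpd_te >= 1.4) "good" else "poor",
      treatment = treatment,
      model_type = if (is_plsr) "plsr" else "lasso",
      hyperparameter = if (is_plsr) as.numeric(model@n_lvs)
                       else model@alpha,
      selection = selection,
      n_bands = length(model@coefficients))
}
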