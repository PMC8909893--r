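## The full study grid: 8 pre-treatments x {PLSR, LASSO} plus
## 8 x {beta-coefficient, VIP} wavelength-selected PLSR refits = 32 model
## cells, all sharing one train/test split.

.gridCell <- function(expr, cell) {
  tryCatch(list(value = expr(), error = ""),
           error = function(e) list(value = NULL,
                                    error = conditionMessage(e)))
}

.emptyRow <- function(treatment, model, selection, error) {
  data.frame(treatment = treatment, model = model, selection = selection,
             hyperparameter = NA_real_, n_bands = NA_integer_,
             r2_train = NA_real_, r2_test = NA_real_,
             rmse_train = NA_real_, rmse_test = NA_real_,
             rpd_train = NA_real_, rpd_test = NA_real_, lod = NA_real_,
             quality = NA_character_, error = error,
             stringsAsFactors = FALSE)
}

#' Run the pre-treatment x model grid
#'
#' For every pre-treatment: fits PLSR with leave-one-out latent-variable
#' selection and LASSO with leave-one-out penalty selection on the treated
#' training spectra and evaluates both splits; then derives
#' beta-coefficient and VIP wavelength selections from the PLSR fit,
#' refits on the retained bands and evaluates those too. With the
#' canonical eight treatments this yields 32 report rows: 16 without
#' selection (8 PLSR + 8 LASSO) followed by 16 with selection (8
#' beta-coefficient + 8 VIP).
#'
#' All cells share one [SplitSpec-class] (the study splits once, then
#' compares models), and the run is deterministic given the dataset and
#' split seed. A failing cell is recorded in its row's `error` field and
#' the grid continues.
#'
#' @param dataset a [SpectralDataset-class] of untreated mean spectra.
#' @param treatments character vector of treatment tags (default
#'   [canonicalTreatments()]).
#' @param split a [SplitSpec-class]; default `splitDataset(dataset)`
#'   (fraction 0.2, seed 20).
#' @param max_lvs,n_alpha hyperparameter search sizes.
#' @param sg_window,sg_polyorder_1,sg_polyorder_2 Savitzky-Golay controls
#'   for the SG1/SG2 treatments.
#' @return A [GridResult-class].
#' @seealso [bestModels()], [writeGridResults()], [exportScatter()]
#' @export
runGrid <- function(dataset, treatments = canonicalTreatments(),
                    split = NULL, max_lvs = 20L, n_alpha = 50L,
                    sg_window = 11L, sg_polyorder_1 = 2L,
                    sg_polyorder_2 = 3L) {
  stopifnot(is(dataset, "SpectralDataset"))
  if (ncol(dataset) < 10L) stop("need at least 10 samples")
  if (is.null(split)) split <- splitDataset(dataset)
  validObject(split)
  train <- dataset[, split@train_indices]
  test <- dataset[, split@test_indices]
  rows <- list()
  sel_rows <- list()
  models <- list()
  for (tag in treatments) {
    tr <- tryCatch(
      applyTreatment(train, test, tag, sg_window = sg_window,
                     sg_polyorder_1 = sg_polyorder_1,
                     sg_polyorder_2 = sg_polyorder_2),
      error = function(e) e)
    if (inherits(tr, "error")) {
      msg <- conditionMessage(tr)
      rows[[length(rows) + 1L]] <- .emptyRow(tag, "plsr", "none", msg)
      rows[[length(rows) + 1L]] <- .emptyRow(tag, "lasso", "none", msg)
      sel_rows[[length(sel_rows) + 1L]] <-
        .emptyRow(tag, "plsr", "beta_coefficient", msg)
      sel_rows[[length(sel_rows) + 1L]] <- .emptyRow(tag, "plsr", "vip", msg)
      next
    }
    plsr_cell <- .gridCell(function() {
      m <- selectNumLVs(tr$train, max_lvs = max_lvs)
      list(model = m,
           report = evaluateModel(m, tr$train, NULL, tr$test,
                                  treatment = tag))
    })
    if (plsr_cell$error == "") {
      models[[paste0(tag, ".plsr")]] <- plsr_cell$value$model
      r <- as.data.frame(plsr_cell$value$report)
      r$error <- ""
      rows[[length(rows) + 1L]] <- r
    } else {
      rows[[length(rows) + 1L]] <- .emptyRow(tag, "plsr", "none",
                                             plsr_cell$error)
    }
    lasso_cell <- .gridCell(function() {
      m <- selectAlpha(tr$train, n_alpha = n_alpha)
      list(model = m,
           report = evaluateModel(m, tr$train, NULL, tr$test,
                                  treatment = tag))
    })
    if (lasso_cell$error == "") {
      models[[paste0(tag, ".lasso")]] <- lasso_cell$value$model
      r <- as.data.frame(lasso_cell$value$report)
      r$error <- ""
      rows[[length(rows) + 1L]] <- r
    } else {
      rows[[length(rows) + 1L]] <- .emptyRow(tag, "lasso", "none",
                                             lasso_cell$error)
    }
    for (sel in c("beta_coefficient", "vip")) {
      cell <- .gridCell(function() {
        if (plsr_cell$error != "")
          stop("parent PLSR fit failed: ", plsr_cell$error)
        s <- if (sel == "beta_coefficient")
          betaSelect(plsr_cell$value$model)
        else vipSelect(plsr_cell$value$model)
        refitOnSelection(tr$train, NULL, tr$test, NULL, s,
                         max_lvs = max_lvs, treatment = tag)
      })
      if (cell$error == "") {
        models[[paste0(tag, ".plsr.", sel)]] <- cell$value$model
        r <- as.data.frame(cell$value$report)
        r$error <- ""
        sel_rows[[length(sel_rows) + 1L]] <- r
      } else {
        sel_rows[[length(sel_rows) + 1L]] <-
          .emptyRow(tag, "plsr", sel, cell$error)
      }
    }
  }
  results <- do.call(rbind, c(rows, sel_rows))
  rownames(results) <- NULL
  n_fail <- sum(results$error != "")
  if (n_fail > 0)
    warning(n_fail, " of ", nrow(results), " grid cells failed")
  manifest <- list(
    n_samples = ncol(dataset),
    n_bands = nrow(dataset),
    treatments = treatments,
    split = list(test_fraction = split@test_fraction, seed = split@seed,
                 n_train = length(split@train_indices),
                 n_test = length(split@test_indices)),
    max_lvs = as.integer(max_lvs), n_alpha = as.integer(n_alpha),
    sg = list(window = as.integer(sg_window),
              polyorder_1 = as.integer(sg_polyorder_1),
              polyorder_2 = as.integer(sg_polyorder_2)),
    config_hash = objectHash(list(treatments, split@test_fraction,
                                  split@seed, max_lvs, n_alpha, sg_window,
                                  sg_polyorder_1, sg_polyorder_2)),
    versions = list(gingerHSI = as.character(packageVersion("gingerHSI")),
                    R = R.version.string))
  new("GridResult", results = results, models = models, split = split,
      manifest = manifest)
}

#' Best model per family
#'
#' Picks the row maximising the criterion (testing RPD by default) within
#' each model family: PLSR without selection, LASSO, PLSR with
#' beta-coefficient selection, and PLSR with VIP selection. Ties go to the
#' first row in canonical treatment order.
#'
#' @param grid a [GridResult-class].
#' @param criterion results column to maximise (default `"rpd_test"`).
#' @return data.frame with one row per family.
#' @export
bestModels <- function(grid, criterion = "rpd_test") {
  stopifnot(is(grid, "GridResult"))
  res <- grid@results[grid@results$error == "", , drop = FALSE]
  if (!nrow(res)) stop("no successful grid cells")
  fam <- paste(res$model, res$selection, sep = "/")
  out <- do.call(rbind, lapply(split(res, fam), function(d)
    d[which.max(d[[criterion]]), , drop = FALSE]))
  out <- out[order(match(paste(out$model, out$selection, sep = "/"),
                         c("plsr/none", "lasso/none",
                           "plsr/beta_coefficient", "plsr/vip"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measured-vs-predicted scatter table
#'
#' One row per sample with its measured ratio, model prediction and split
#' label — the data behind a measured-vs-predicted calibration plot.
#'
#' @param model a fitted [PLSRModel-class] or [LassoModel-class].
#' @param x_train,y_train,x_test,y_test the two (treated) splits.
#' @param path optional CSV output path.
#' @return data.frame with columns `measured`, `predicted`, `split`.
#' @export
exportScatter <- function(model, x_train, y_train = NULL, x_test,
                          y_test = NULL, path = NULL) {
  dtr <- .asXy(x_train, y_train)
  dte <- .asXy(x_test, y_test)
  out <- rbind(
    data.frame(measured = dtr$y, predicted = predict(model, dtr$X),
               split = "train", stringsAsFactors = FALSE),
    data.frame(measured = dte$y, predicted = predict(model, dte$X),
               split = "test", stringsAsFactors = FALSE))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Write grid outputs to a directory
#'
#' Writes `grid_results.csv` (one row per model cell),
#' `best_models.json` and `manifest.json`.
#'
#' @param grid a [GridResult-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeGridResults <- function(grid, dir) {
  stopifnot(is(grid, "GridResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(grid@results, file.path(dir, "grid_results.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bestModels(grid),
                       file.path(dir, "best_models.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(grid@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
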