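# Composition calibration surface: pretreat one modality's training
# spectra, cross-validate the component count, optionally run GA window
# selection, and replay the whole fitted chain on held-out spectra.

#' Calibrate a composition model on one spectral modality
#'
#' Applies the pretreatment recipe (fitting its state on the training set),
#' chooses the latent-variable count by 30-split contiguous-block
#' cross-validation (smallest count within 2 % of the minimum RMSECV),
#' optionally refines the channel selection with the genetic algorithm, and
#' fits the final NIPALS PLS1 model.
#'
#' @param spectra Raw training [spectrum_set()].
#' @param y Training response (% w/w drug or polymer content).
#' @param analyte Label, `"dr"` or `"hpmc"`.
#' @param recipe Pretreatment recipe; defaults to the modality's standard
#'   recipe.
#' @param max_lv Largest component count cross-validated.
#' @param n_splits Contiguous-block CV splits.
#' @param ga `FALSE`, `TRUE` (default [ga_config()]), or a [ga_config()].
#' @param seed Seed for the GA.
#' @return An object of class `composition_calibration`: recipe + fitted
#'   state, channel mask, `pls_model`, CV curve, chosen `n_lv`, metrics on
#'   the calibration set.
#' @export
calibrate_composition <- function(spectra, y, analyte = "dr",
                                  recipe = default_recipe(spectra$modality),
                                  max_lv = 10, n_splits = 30, ga = FALSE,
                                  seed = 1L) {
  pre <- apply_recipe(spectra, recipe)
  X <- pre$spectra$intensities
  max_lv <- min(max_lv, nrow(X) - 1L, ncol(X))
  ga_result <- NULL
  if (isTRUE(ga)) ga <- ga_config()
  if (inherits(ga, "ga_config")) {
    ga_result <- ga_select(X, y, ga, seed = seed)
    mask <- ga_result$mask
    model <- ga_result$model
    cv <- contiguous_block_cv(X[, mask, drop = FALSE], y,
                              min(ga$max_lv, sum(mask), nrow(X) - 1L),
                              n_splits = n_splits)
    n_lv <- model$n_lv
  } else {
    mask <- rep(TRUE, ncol(X))
    cv <- contiguous_block_cv(X, y, max_lv, n_splits = n_splits)
    n_lv <- choose_n_lv(cv$rmsecv)
    model <- pls_fit(X, y, n_lv)
  }
  metrics <- pls_metrics(model, X[, mask, drop = FALSE], y, cv = cv)
  structure(list(analyte = analyte, modality = spectra$modality,
                 recipe = recipe, state = pre$state, mask = mask,
                 model = model, cv = cv, n_lv = n_lv, metrics = metrics,
                 wavenumbers = pre$spectra$wavenumbers,
                 ga = ga_result),
            class = "composition_calibration")
}

#' Predict composition from raw held-out spectra
#'
#' Replays the calibration's pretreatment chain (stored MSC reference and
#' column means), applies the channel mask, and predicts with the fitted
#' PLS model.
#'
#' @param calibration A [calibrate_composition()] result.
#' @param spectra Raw [spectrum_set()] of held-out tablets.
#' @return Named numeric vector of predicted % w/w.
#' @export
predict_composition <- function(calibration, spectra) {
  pre <- apply_recipe(spectra, calibration$recipe, state = calibration$state)
  if (!isTRUE(all.equal(pre$spectra$wavenumbers, calibration$wavenumbers)))
    stop("channel-grid mismatch between calibration and new spectra")
  X <- pre$spectra$intensities[, calibration$mask, drop = FALSE]
  stats::setNames(predict(calibration$model, X), pre$spectra$sample_ids)
}
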