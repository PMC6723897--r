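# End-to-end orchestration on synthetic data: generate -> preprocess ->
# composition PLS -> profile models (ANN + direct-PLS baseline) ->
# f2/RMSEP evaluation and the model-comparison table, with a reproducible
# run manifest and CSV/JSON artifacts.

#' Pipeline configuration
#'
#' Two built-in profiles: `"quick"` (desk scale: 5 replicate runs, hidden
#' neurons 1/3/5, Bayesian-regularization trainer, GA off) and `"full"`
#' (study scale: 100 runs, hidden 1..10, both trainers, GA on).
#'
#' @param profile `"quick"` or `"full"`.
#' @param seed Master seed; every stage's randomness derives from it.
#' @param generator A [simulator_config()].
#' @param sources Input sources to evaluate: any of `"raman"` (both
#'   analytes from Raman transmission), `"nir"` (both from NIR
#'   transmission), `"nir_raman"` (drug from Raman, polymer from NIR).
#' @param trainer,runs,hidden_values,max_epochs Neuron-sweep settings
#'   (override the profile defaults).
#' @param ga GA variable selection for the composition models.
#' @param max_lv Largest PLS component count cross-validated.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("quick", "full"), seed = 1L,
                            generator = simulator_config(),
                            sources = c("raman", "nir", "nir_raman"),
                            trainer = NULL, runs = NULL, hidden_values = NULL,
                            max_epochs = NULL, ga = NULL, max_lv = 10) {
  profile <- match.arg(profile)
  quick <- profile == "quick"
  structure(list(
    profile = profile, seed = as.integer(seed), generator = generator,
    sources = match.arg(sources, several.ok = TRUE),
    trainer = trainer %||% if (quick) "BR" else "both",
    runs = runs %||% if (quick) 5L else 100L,
    hidden_values = hidden_values %||% if (quick) c(1L, 3L, 5L) else 1:10,
    max_epochs = max_epochs %||% if (quick) 120L else 200L,
    ga = ga %||% !quick,
    max_lv = max_lv
  ), class = "pipeline_config")
}

#' Run the full surrogate pipeline on synthetic data
#'
#' Executes the cascade: dataset generation; pretreatment + PLS composition
#' calibration for drug and polymer on Raman and NIR transmission spectra;
#' composition prediction for the held-out test tablets; hidden-neuron
#' sweep of the profile network (training inputs are nominal composition +
#' measured force, test inputs the PLS-predicted composition + measured
#' force) and the direct-PLS baseline, per input source; f2/RMSEP reports
#' against both the measured and the simulator ground-truth test profiles;
#' and the model-comparison table. Deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: artifacts (CSV/JSON) are written
#'   there (created if needed).
#' @return A list: `data`, `calibrations`, `composition_predictions`,
#'   `sweeps`, `ann_reports`, `pls_reports` (vs measured profiles),
#'   `ann_reports_true`, `pls_reports_true` (vs noise-free truth),
#'   `comparison` (Table-style mean-f2 layout), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage_seeds <- derive_seeds(config$seed, 8L)
  data <- generate_dataset(config$generator, seed = stage_seeds[1])
  tab <- data$tablets
  train <- tab$role == "train"; test <- tab$role == "test"

  # composition calibrations on the transmission modalities
  calib <- list()
  for (mod in c("raman_trans", "nir_trans")) {
    s_train <- subset_spectra(data$spectra[[mod]], train)
    for (analyte in c("dr", "hpmc")) {
      y <- if (analyte == "dr") tab$dr_true[train] else tab$hpmc_true[train]
      calib[[paste(mod, analyte, sep = ".")]] <-
        calibrate_composition(s_train, y, analyte = analyte,
                              max_lv = config$max_lv, ga = config$ga,
                              seed = stage_seeds[2])
    }
  }

  # test-set composition predictions per source
  predict_from <- function(mod, analyte) {
    predict_composition(calib[[paste(mod, analyte, sep = ".")]],
                        subset_spectra(data$spectra[[mod]], test))
  }
  comp_pred <- list(
    raman = cbind(dr = predict_from("raman_trans", "dr"),
                  hpmc = predict_from("raman_trans", "hpmc")),
    nir = cbind(dr = predict_from("nir_trans", "dr"),
                hpmc = predict_from("nir_trans", "hpmc")),
    nir_raman = cbind(dr = predict_from("raman_trans", "dr"),
                      hpmc = predict_from("nir_trans", "hpmc"))
  )[config$sources]

  X_train <- cbind(dr = tab$dr_nominal[train], hpmc = tab$hpmc_nominal[train],
                   force = tab$force_measured[train])
  Y_train <- data$profiles[train, , drop = FALSE]
  Y_test <- data$profiles[test, , drop = FALSE]
  Y_test_true <- data$profiles_true[test, , drop = FALSE]
  trainers <- if (config$trainer == "both") c("BR", "LM") else config$trainer

  sweeps <- list(); ann_reports <- list(); pls_reports <- list()
  ann_reports_true <- list(); pls_reports_true <- list()
  for (src in config$sources) {
    X_test <- cbind(comp_pred[[src]],
                    force = tab$force_measured[test])
    for (tr in trainers) {
      key <- if (length(trainers) > 1) paste(src, tolower(tr), sep = ".") else src
      sweep <- neuron_sweep(X_train, Y_train, X_test, Y_test, trainer = tr,
                            runs = config$runs,
                            hidden_values = config$hidden_values,
                            seed = stage_seeds[3], max_epochs = config$max_epochs)
      ann_pred <- ann_forward(sweep$best$net, X_test)
      sweeps[[key]] <- sweep
      ann_reports[[key]] <- f2_report(ann_pred, Y_test, tab$tablet_id[test],
                                      model = paste0("ANN-", tr, " (", src, ")"))
      ann_reports_true[[key]] <- f2_report(ann_pred, Y_test_true,
                                           tab$tablet_id[test],
                                           model = paste0("ANN-", tr, " (", src,
                                                          ", vs truth)"))
    }
    pls_model <- pls_direct_fit(X_train, Y_train, n_lv = 3)
    pls_pred <- predict(pls_model, X_test)
    pls_reports[[src]] <- f2_report(pls_pred, Y_test, tab$tablet_id[test],
                                    model = paste0("PLS (", src, ")"))
    pls_reports_true[[src]] <- f2_report(pls_pred, Y_test_true,
                                         tab$tablet_id[test],
                                         model = paste0("PLS (", src, ", vs truth)"))
  }

  first_key <- function(src) if (length(trainers) > 1)
    paste(src, tolower(trainers[1]), sep = ".") else src
  comparison <- data.frame(
    model = c("ANN", "PLS"),
    do.call(cbind, stats::setNames(lapply(config$sources, function(src)
      c(ann_reports[[first_key(src)]]$mean_f2, pls_reports[[src]]$mean_f2)),
      config$sources)),
    check.names = FALSE, stringsAsFactors = FALSE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("dissosurrogate")),
    profile = config$profile, master_seed = config$seed,
    stage_seeds = stage_seeds,
    sources = config$sources, trainer = config$trainer,
    runs = config$runs, hidden_values = config$hidden_values,
    max_epochs = config$max_epochs, ga = config$ga,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(data = data, calibrations = calib,
                 composition_predictions = comp_pred, sweeps = sweeps,
                 ann_reports = ann_reports, pls_reports = pls_reports,
                 ann_reports_true = ann_reports_true,
                 pls_reports_true = pls_reports_true,
                 comparison = comparison, manifest = manifest)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

# internal: row-subset a spectrum_set
subset_spectra <- function(s, idx) {
  spectrum_set(s$wavenumbers, s$intensities[idx, , drop = FALSE],
               s$sample_ids[idx], s$modality, s$provenance)
}

#' Write / read pipeline artifacts
#'
#' Tablets and profiles go to CSV (profiles: first column `time_min`, one
#' column per tablet), spectra to one CSV per modality, f2 reports and the
#' comparison table to CSV, and the manifest to JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$data$tablets, file.path(out_dir, "tablets.csv"),
                   row.names = FALSE)
  write_profiles_csv(result$data$profiles, result$data$times,
                     file.path(out_dir, "profiles_measured.csv"))
  write_profiles_csv(result$data$profiles_true, result$data$times,
                     file.path(out_dir, "profiles_true.csv"))
  for (mod in names(result$data$spectra))
    write_spectra_csv(result$data$spectra[[mod]],
                      file.path(out_dir, paste0("spectra_", mod, ".csv")))
  for (key in names(result$ann_reports))
    utils::write.csv(result$ann_reports[[key]]$per_tablet,
                     file.path(out_dir, paste0("f2_ann_", gsub("\\.", "_", key),
                                               ".csv")), row.names = FALSE)
  for (key in names(result$pls_reports))
    utils::write.csv(result$pls_reports[[key]]$per_tablet,
                     file.path(out_dir, paste0("f2_pls_", key, ".csv")),
                     row.names = FALSE)
  utils::write.csv(result$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname write_run_artifacts
#' @param profiles Profiles matrix (rows = tablets).
#' @param times Time grid (minutes).
#' @param path CSV path.
#' @export
write_profiles_csv <- function(profiles, times, path) {
  df <- data.frame(time_min = times, t(profiles), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_run_artifacts
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(colnames(df)[1], "time_min"))
    stop("profile CSV must have 'time_min' as its first column: ", path)
  times <- df$time_min
  if (anyNA(times) || any(diff(times) <= 0))
    stop("time column must be strictly increasing in ", path)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  if (!is.numeric(m)) stop("non-numeric dissolution cells in ", path)
  colnames(m) <- times
  list(times = times, profiles = m)
}
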