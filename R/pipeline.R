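#' Assemble a full run configuration
#'
#' Bundles the simulation, preprocessing and classifier configurations with
#' the output location and a master seed. Serializable to YAML with
#' [write_run_config()] / [read_run_config()]; every file a run writes carries
#' a hash of this configuration so artifacts from different configurations are
#' detected when mixed.
#'
#' @param output_dir Directory run artifacts are written to.
#' @param sim A [sim_config()].
#' @param pre A [preprocess_config()].
#' @param svm An [svm_config()].
#' @param seed Master seed; overrides `sim$seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir = ".", sim = sim_config(),
                       pre = preprocess_config(), svm = svm_config(),
                       seed = sim$seed) {
  sim$seed <- as.integer(seed)
  structure(list(output_dir = output_dir, sim = sim, pre = pre, svm = svm,
                 seed = as.integer(seed)),
            class = "run_config")
}

# canonical serializable form; also what write_run_config() writes
config_payload <- function(config) {
  ax <- config$sim$axis
  list(
    output_dir = config$output_dir,
    seed = config$seed,
    axis = list(n_points = ax$n_points, sweep_width = ax$sweep_width,
                spectrometer_freq = ax$spectrometer_freq,
                carrier_ppm = ax$carrier_ppm),
    sim = unclass(config$sim[setdiff(names(config$sim), "axis")]),
    pre = unclass(config$pre),
    svm = unclass(config$svm)
  )
}

# hash of the canonical YAML text, so equal-valued configs hash equally no
# matter how their vectors were constructed
config_hash <- function(config) {
  p <- config_payload(config)
  p$output_dir <- NULL # artifact location does not define the analysis
  rlang::hash(yaml::as.yaml(p))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config_payload(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  p <- yaml::read_yaml(path)
  ax <- do.call(ppm_axis, p$axis)
  run_config(
    output_dir = p$output_dir,
    sim = do.call(sim_config, c(list(axis = ax), p$sim)),
    pre = do.call(preprocess_config, p$pre),
    svm = do.call(svm_config, p$svm),
    seed = p$seed
  )
}

#' Simulate a cohort and write it to disk
#'
#' Writes one spectrum text file per sample plus a `manifest.csv`
#' (`sample_id`, `label`, `file`, `config_hash`).
#'
#' @param config A [run_config()].
#' @param basis Metabolite basis ([default_basis()]).
#' @param dir Output directory (default `config$output_dir`).
#' @return The manifest tibble, invisibly.
#' @export
simulate_to_dir <- function(config = run_config(), basis = default_basis(),
                            dir = config$output_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$sim$n_mut + config$sim$n_wt == 0L) {
    warn("empty cohort requested; writing manifest only.")
    manifest <- tibble::tibble(sample_id = character(), label = character(),
                               file = character(), config_hash = character())
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    return(invisible(manifest))
  }
  cohort <- simulate_cohort(basis, config$sim)
  hash <- config_hash(config)
  ids <- unique(cohort$sample_id)
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    one <- new_mrs_spectra(cohort[cohort$sample_id == ids[i], ],
                           spectra_axis(cohort))
    files[i] <- file.path(dir, paste0(ids[i], ".txt"))
    write_spectrum_txt(one, files[i])
  }
  manifest <- tibble::tibble(
    sample_id = ids,
    label = cohort$label[match(ids, cohort$sample_id)],
    file = basename(files),
    config_hash = hash
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  message(sprintf("wrote %d spectra to %s (seed %d, config %s)",
                  length(ids), dir, config$seed, hash))
  invisible(manifest)
}

#' Read a cohort previously written by [simulate_to_dir()]
#'
#' @param dir Directory containing `manifest.csv` and spectrum files.
#' @param expect_hash Optional config hash; if the manifest was written under
#'   a different configuration the read is refused.
#' @return An `mrs_spectra` tibble.
#' @export
read_cohort_dir <- function(dir, expect_hash = NULL) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  if (!is.null(expect_hash) && "config_hash" %in% names(manifest) &&
      nrow(manifest) && any(manifest$config_hash != expect_hash)) {
    abort("manifest was written under a different configuration; refusing to mix artifacts.",
          class = "gliomrs_config_mismatch")
  }
  read_cohort_txt(file.path(dir, manifest$file))
}

#' Run the full pipeline: simulate (or load), preprocess, classify, report
#'
#' Chains [simulate_cohort()] (or [read_cohort_dir()] when `input_dir` is
#' given), [preprocess_cohort()], [nested_loocv()] and [performance_report()],
#' writing the feature matrix, per-sample predictions, selected-feature
#' frequencies and the JSON report into `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param basis Metabolite basis used for simulation and annotation.
#' @param input_dir Optional directory of measured/simulated spectra; when
#'   `NULL` a cohort is simulated from `config$sim`.
#' @return The `mrs_performance` report, invisibly; the `nested_loocv` result
#'   is attached as attribute `"cv"`.
#' @export
run_pipeline <- function(config = run_config(), basis = default_basis(),
                         input_dir = NULL) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  spectra <- if (is.null(input_dir)) {
    simulate_cohort(basis, config$sim)
  } else {
    read_cohort_dir(input_dir)
  }
  if (any(spectra$label == "unknown")) {
    abort("cross-validation needs labeled spectra; found label 'unknown'.",
          class = "gliomrs_label_error")
  }
  features <- preprocess_cohort(spectra, config$pre)
  cv <- nested_loocv(features, config$svm)
  report <- performance_report(cv, table = assignment_table(basis))

  write_feature_matrix_csv(features, file.path(config$output_dir, "features.csv"))
  pred <- cv$predictions
  pred$config_hash <- hash
  readr::write_csv(pred, file.path(config$output_dir, "cv_predictions.csv"))
  sel <- report$selection
  sel$config_hash <- hash
  readr::write_csv(sel, file.path(config$output_dir, "selected_features.csv"))
  write_report_json(report, file.path(config$output_dir, "report.json"))
  write_run_config(config, file.path(config$output_dir, "config.yaml"))

  attr(report, "cv") <- cv
  invisible(report)
}

#' Train once on a labeled cohort and predict new spectra
#'
#' Trains on the full labeled training set (feature count chosen by the inner
#' leave-one-out loop, features ranked on the full training set) and predicts
#' each new spectrum. New spectra that fail preprocessing (for instance an
#' all-zero spectrum that cannot be normalized) are reported per sample
#' without aborting the batch.
#'
#' @param train_features A labeled `mrs_features` tibble (stage `"log2"`).
#' @param new_spectra An `mrs_spectra` tibble of unlabeled spectra (may be
#'   empty).
#' @param pre A [preprocess_config()].
#' @param svm An [svm_config()].
#' @return A tibble with `sample_id`, `decision`, `predicted`, `error`
#'   (`NA` on success).
#' @export
predict_new <- function(train_features, new_spectra,
                        pre = preprocess_config(), svm = svm_config()) {
  k <- choose_k_inner_cv(train_features, svm)$k
  ranking <- rank_features_ttest(train_features, svm$positive_class)
  model <- train_linear_svm(train_features, selected = ranking$bin[seq_len(k)],
                            config = svm)
  ids <- unique(new_spectra$sample_id)
  if (!length(ids)) {
    return(tibble::tibble(sample_id = character(), decision = numeric(),
                          predicted = character(), error = character()))
  }
  ax <- spectra_axis(new_spectra)
  rows <- lapply(ids, function(id) {
    one <- new_mrs_spectra(new_spectra[new_spectra$sample_id == id, ], ax)
    tryCatch({
      f <- preprocess_cohort(one, pre)
      p <- predict(model, f)
      tibble::tibble(sample_id = id, decision = p$decision,
                     predicted = p$predicted, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(sample_id = id, decision = NA_real_,
                     predicted = NA_character_,
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_rows(rows)
}
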