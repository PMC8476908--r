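# Single-call study replication: simulate -> compare -> features -> train
# (ML + CNN) -> evaluate -> report.

#' Replication run configuration
#'
#' Bundles every knob of the full pipeline so a run is reproducible from its
#' configuration alone.
#'
#' @param sim a [simulation_config()] (cohort conditions and master seed).
#' @param ssim an [ssim_config()].
#' @param dd_disc,ssim_disc [disc_config()]s for DD and SSIM-component maps.
#' @param pearson_threshold Pearson filter cutoff.
#' @param split_seed seed of the patient-level 80/20 split (shared by every
#'   model and the CNN so all see the same patients).
#' @param models ML model kinds to run.
#' @param ml_configs input configurations to run.
#' @param tasks classification tasks to run.
#' @param include_cnn also train/evaluate the four-branch CNN per task.
#' @param cnn a [train_config()] for the CNN runs.
#' @param grids optional named list of grid overrides per model kind.
#' @param out_dir optional directory for CSV/JSON reports.
#' @return A `run_config` object.
#' @export
run_config <- function(sim = simulation_config(),
                       ssim = ssim_config(),
                       dd_disc = disc_config("width", bin_width = 25),
                       ssim_disc = disc_config("count", bin_count = 32),
                       pearson_threshold = 0.1,
                       split_seed = 1L,
                       models = MODEL_KINDS,
                       ml_configs = c("ml1", "ml2", "ml3"),
                       tasks = TASKS,
                       include_cnn = TRUE,
                       cnn = train_config(),
                       grids = list(),
                       out_dir = NULL) {
  structure(list(sim = sim, ssim = ssim, dd_disc = dd_disc,
                 ssim_disc = ssim_disc,
                 pearson_threshold = pearson_threshold,
                 split_seed = as.integer(split_seed), models = models,
                 ml_configs = ml_configs, tasks = tasks,
                 include_cnn = include_cnn, cnn = cnn, grids = grids,
                 out_dir = out_dir),
            class = "run_config")
}

#' Replicate the full classification study on a synthetic cohort
#'
#' Generates the cohort, computes comparison maps and feature matrices,
#' runs every requested (input configuration, task, model) ML experiment
#' plus the CNN, and assembles accuracy/AUC and per-class metric tables
#' (AUC only for the binary tasks). With an `out_dir`, the tables, the
#' confusion matrices and a provenance log are written as CSV/JSON.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pregenerated cohort (skips simulation).
#' @return A list with `results` (one row per experiment: accuracy, AUC),
#'   `per_class` (type-3 style per-class metrics), `experiments` (the raw
#'   objects) and `cohort_summary`.
#' @export
replicate_study <- function(config = run_config(), cohort = NULL) {
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- generate_cohort(config$sim)
  message(sprintf("[%.1fs] cohort: %d maps", dt(t0), nrow(cohort)))

  features <- lapply(stats::setNames(config$ml_configs, config$ml_configs),
                     function(mlc)
    build_feature_matrix(cohort, mlc, ssim_cfg = config$ssim,
                         dd_disc = config$dd_disc,
                         ssim_disc = config$ssim_disc))
  message(sprintf("[%.1fs] features extracted", dt(t0)))

  experiments <- list()
  for (mlc in config$ml_configs) {
    for (task in config$tasks) {
      for (mk in config$models) {
        ex <- run_experiment(ml_config = mlc, task = task, model_kind = mk,
                             seed = config$split_seed,
                             features = features[[mlc]],
                             pearson_threshold = config$pearson_threshold,
                             grid = config$grids[[mk]])
        experiments[[paste(mlc, task, mk, sep = "_")]] <- ex
      }
    }
    message(sprintf("[%.1fs] ML experiments for %s done", dt(t0), mlc))
  }

  if (config$include_cnn) {
    split <- split_by_patient(cohort, config$split_seed)
    cmp <- cohort_comparisons(cohort, config$ssim)
    err <- cohort[cohort$role == "error", ]
    tr_i <- which(err$patient_id %in% split$train)
    te_i <- which(err$patient_id %in% split$test)
    for (task in config$tasks) {
      labels <- as.integer(err[[task]])
      n_classes <- if (task == "type3") 8L else 2L
      model <- train_cnn(cmp[tr_i], labels[tr_i], n_classes,
                         cfg = config$cnn)
      pred <- predict_cnn(model, cmp[te_i])
      predictions <- dplyr::bind_cols(
        err[te_i, c("patient_id", "serial")],
        tibble::tibble(truth = labels[te_i]), pred)
      experiments[[paste("cnn", task, sep = "_")]] <-
        structure(list(model = model, predictions = predictions,
                       split = split, ml_config = "cnn", task = task,
                       model_kind = "cnn", seed = config$split_seed),
                  class = "epid_experiment")
      message(sprintf("[%.1fs] CNN %s done", dt(t0), task))
    }
  }

  results <- dplyr::bind_rows(lapply(experiments, glance))
  per_class <- dplyr::bind_rows(lapply(
    Filter(function(e) e$task == "type3", experiments), function(e)
      dplyr::mutate(precision_recall_f1(confusion(e$predictions,
                                                  classes = 1:8)),
                    ml_config = e$ml_config, model = e$model_kind,
                    .before = 1)))

  out <- list(results = results, per_class = per_class,
              experiments = experiments,
              cohort_summary = dplyr::count(cohort, .data$patient_id,
                                            .data$role))
  if (!is.null(config$out_dir)) write_report(out, config)
  out
}

dt <- function(t0) as.numeric(Sys.time() - t0, units = "secs")

# Comparison maps of every error record against its patient's baseline.
cohort_comparisons <- function(cohort, ssim_cfg = ssim_config()) {
  base <- cohort[cohort$role == "baseline", ]
  base_by_pat <- stats::setNames(base$map, base$patient_id)
  err <- cohort[cohort$role == "error", ]
  lapply(seq_len(nrow(err)), function(i)
    ssim_components(base_by_pat[[err$patient_id[i]]], err$map[[i]], ssim_cfg))
}

write_report <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out$results, file.path(config$out_dir, "results.csv"))
  if (nrow(out$per_class))
    readr::write_csv(out$per_class,
                     file.path(config$out_dir, "per_class_metrics.csv"))
  for (nm in names(out$experiments)) {
    cm <- confusion(out$experiments[[nm]]$predictions)
    utils::write.csv(unclass(cm),
                     file.path(config$out_dir,
                               paste0("confusion_", nm, ".csv")))
  }
  provenance <- list(
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("epidshift")),
    master_seed = config$sim$master_seed,
    split_seed = config$split_seed,
    n_patients = config$sim$n_patients,
    image_size = config$sim$image_size)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(config$out_dir)
}
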