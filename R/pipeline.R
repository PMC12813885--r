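# End-to-end workflow: develop (phantom + training) -> calibrate -> deploy.

#' Assemble a full run configuration
#'
#' Bundles the stage configurations with the pipeline-level knobs. Every
#' stochastic stage derives its own seed from the master seed by stage-name
#' hashing, so the master seed alone reproduces a run and adding a stage
#' never shifts another stage's randomness.
#'
#' @param phantom A [phantom_config()].
#' @param model A [model_config()] (its `structure_code_length` must match
#'   the phantom's structure count).
#' @param train A [train_config()].
#' @param n_train,n_val,n_test Cohort split sizes in patients.
#' @param T Monte-Carlo dropout passes at inference (default 30).
#' @param target_recall Calibration sensitivity target (default 0.98).
#' @param overrides Optional named per-structure target overrides.
#' @param seed Master seed.
#' @return An object of class `cqa_run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       model = model_config(
                         structure_code_length = phantom$n_structures,
                         image_size = phantom$image_size),
                       train = train_config(),
                       n_train = 100, n_val = 20, n_test = 20,
                       T = 30, target_recall = 0.98, overrides = NULL,
                       seed = 1) {
  if (model$structure_code_length != phantom$n_structures)
    abort("model structure_code_length must equal the phantom's n_structures")
  if (model$image_size != phantom$image_size)
    abort("model and phantom image sizes must agree")
  structure(list(phantom = phantom, model = model, train = train,
                 n_train = n_train, n_val = n_val, n_test = n_test,
                 T = as.integer(T), target_recall = target_recall,
                 overrides = overrides, seed = as.integer(seed)),
            class = "cqa_run_config")
}

#' Reference desk-scale experiment configuration
#'
#' The package's standard synthetic end-to-end experiment: a 100/20/20
#' patient phantom cohort with three structures on the default 64 px grid,
#' the small residual backbone, 20 training epochs at batch 64, and T = 10
#' Monte-Carlo passes. The learning rate is 1e-3: the desk-scale network
#' trains for only ~800 Adam steps, so the reference schedule (1e-4 with
#' decays every 100 epochs, sized for long GPU runs) is scaled up
#' accordingly. Intended to complete in minutes on one CPU.
#'
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
reference_run_config <- function(seed = 1) {
  run_config(
    phantom = phantom_config(),
    model = model_config("small_resnet", image_size = 64,
                         structure_code_length = 3),
    train = train_config(initial_lr = 1e-3, epochs = 20, batch_size = 64),
    n_train = 100, n_val = 20, n_test = 20,
    T = 10, target_recall = 0.98, seed = seed)
}

#' Run the full QA pipeline
#'
#' Executes, in order: phantom cohort generation, frozen balanced
#' validation/test set construction, model training, Monte-Carlo validation
#' predictions, per-structure threshold calibration, test predictions,
#' accept/flag decisions, and the metric reports. When `out_dir` is given,
#' every stage's artifact is persisted (CSV for tables, JSON for structured
#' outputs, RDS for the model).
#'
#' @param config A [run_config()].
#' @param out_dir Optional artifact directory.
#' @param verbose Print per-epoch training progress?
#' @return A list with the cohort, model, predictions, thresholds,
#'   decisions, metrics, deployment report and binned-performance table.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  master <- config$seed
  phantom_cfg <- config$phantom
  phantom_cfg$seed <- derive_seed(master, "phantom")

  cohort <- generate_cohort(phantom_cfg, config$n_train, config$n_val,
                            config$n_test)
  catalogue <- structure_catalogue(phantom_cfg$structure_names)
  train_pool <- cohort_samples(cohort$train)
  val_set <- build_test_set(cohort_samples(cohort$val), catalogue,
                            seed = derive_seed(master, "valset"))
  test_set <- build_test_set(cohort_samples(cohort$test), catalogue,
                             seed = derive_seed(master, "testset"))

  tc <- config$train
  tc$seed <- derive_seed(master, "train")
  model <- qa_model(config$model, catalogue,
                    seed = derive_seed(master, "init"))
  model <- train_qa_model(model, train_pool, val_set, tc, verbose = verbose)

  val_pred <- mc_predict(model, val_set, T = config$T,
                         seed = derive_seed(master, "mc-val"))
  thresholds <- threshold_table(val_pred, config$target_recall,
                                config$overrides)

  test_pred <- mc_predict(model, test_set, T = config$T,
                          seed = derive_seed(master, "mc-test"))
  decisions <- apply_policy(test_pred, thresholds)
  metrics <- compute_metrics(test_pred, "mean_prob", by_structure = TRUE)
  report <- deployment_report(decisions)
  binned <- binned_performance(test_pred)

  result <- list(config = config, cohort = cohort, model = model,
                 val_predictions = val_pred, thresholds = thresholds,
                 test_predictions = test_pred, decisions = decisions,
                 metrics = metrics, deployment = report, binned = binned,
                 val_perturbations = perturbation_log(val_set),
                 test_perturbations = perturbation_log(test_set))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(model, file.path(out_dir, "model.rds"))
    utils::write.csv(as.data.frame(model$log),
                     file.path(out_dir, "training_log.csv"), row.names = FALSE)
    write_predictions_csv(val_pred, file.path(out_dir, "val_predictions.csv"))
    write_predictions_csv(test_pred, file.path(out_dir, "test_predictions.csv"))
    write_thresholds_json(thresholds, file.path(out_dir, "thresholds.json"))
    dec <- decisions
    dec$per_pass <- NULL
    utils::write.csv(as.data.frame(dec), file.path(out_dir, "decisions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(result$test_perturbations),
                     file.path(out_dir, "perturbations.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(metrics = metrics, deployment = report),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows")
  }
  invisible(result)
}
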