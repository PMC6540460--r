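# End-to-end pipeline: simulate -> augment -> train -> predict -> confidence
# limits -> normality report -> accuracy report, every stage logged and
# reproducible from the configuration's root seed.

# Reports are written at a fixed decimal precision: far below any
# physiological resolution, and it keeps re-runs (including the skip-train
# cached-model path) byte-identical.
write_report <- function(df, path, digits = 6L) {
  df <- as.data.frame(df)
  for (cn in colnames(df)) {
    if (is.numeric(df[[cn]])) df[[cn]] <- round(df[[cn]], digits)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

pipe_log <- function(cfg, level, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[cfg$log_level]] >= levels[[level]]) {
    message(sprintf("[oscibp] %s", sprintf(...)))
  }
}

#' Run the full estimation pipeline
#'
#' Executes every stage on a synthetic cohort and writes the report files to
#' `config$output_dir`:
#'
#' * `measurements.csv` — the simulated cohort;
#' * `augmentation_diagnostics.csv` — per-(subject, column) bootstrap
#'   diagnostics of the training set;
#' * `dbn_model.json` + `training_log.csv` — the first ensemble member and
#'   its loss curves;
#' * `predictions.csv` — per-measurement ensemble estimates on the test set;
#' * `cl_report.csv` — per-subject confidence limits (cohort summary rows
#'   appended as `cl_summary.csv`);
#' * `normality_report.csv` — the cohort normality/independence table;
#' * `evaluation.csv` — ME/SDE/MAE, AAMI flags, BHS bands and grade.
#'
#' Two runs with the same configuration produce byte-identical reports; with
#' `skip_train = TRUE` a previously saved model file is reused and the
#' downstream reports are unchanged.
#'
#' @param config a [run_config()].
#' @param skip_train reuse `model_path` instead of training.
#' @param model_path model file to load when `skip_train` (defaults to the
#'   one inside `output_dir`).
#' @return invisibly, a list with the in-memory stage results and the file
#'   paths.
#' @export
run_pipeline <- function(config, skip_train = FALSE, model_path = NULL) {
  validate_run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  fp <- function(name) file.path(config$output_dir, name)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_numerical(sprintf("pipeline stage `%s` failed: %s", stage,
                             conditionMessage(e)))
    })
  }

  ## 1. simulate
  pipe_log(config, "info", "simulating cohort (%d subjects, seed %s)",
           config$cohort$n_subjects, format(config$cohort$seed))
  cohort <- run_stage("simulate", generate_cohort(config$cohort))
  paths$measurements <- fp("measurements.csv")
  write_measurements(cohort, paths$measurements)

  ## 2. split
  halves <- run_stage("split", split_cohort(cohort, config$n_train_subjects))
  pipe_log(config, "debug", "split: %d train / %d test rows",
           nrow(halves$train), nrow(halves$test))

  ## 3. augmentation diagnostics
  pipe_log(config, "info", "bootstrap augmentation diagnostics (N = %d)",
           config$n_features_boot)
  diag <- run_stage("augment", augmentation_diagnostics(
    halves$train, n_art = config$n_features_boot, n_inner = config$n_inner,
    alpha = config$alpha, seed = derive_seed(config$seed, 3L)))
  paths$augmentation <- fp("augmentation_diagnostics.csv")
  write_report(diag, paths$augmentation)

  ## 4. train (or reload) + 5. predict
  paths$model <- fp("dbn_model.json")
  if (skip_train) {
    mp <- model_path %||% paths$model
    pipe_log(config, "info", "skip-train: loading model from %s", mp)
    model <- run_stage("train", load_dbn(mp))
    fcols <- feature_columns(halves$test)
    est <- run_stage("predict",
                     predict(model, as.matrix(halves$test[, fcols, drop = FALSE])))
    predictions <- data.frame(subject_id = halves$test$subject_id,
                              meas_idx = halves$test$meas_idx,
                              sbp_est = est[, "sbp"], dbp_est = est[, "dbp"],
                              ref_sbp = halves$test$ref_sbp,
                              ref_dbp = halves$test$ref_dbp,
                              stringsAsFactors = FALSE)
  } else {
    pipe_log(config, "info", "training DBN ensemble (%d members)",
             config$train$ensemble_size)
    predictions <- run_stage("train", ensemble_train_predict(
      halves$train, halves$test, config$train,
      n_art = config$n_features_boot, mode = config$augment_mode,
      n_inner = config$n_inner, keep_models = TRUE))
    members <- attr(predictions, "models")
    save_dbn(dbn_ensemble(members), paths$model)
    member1 <- members[[1]]
    logs <- rbind(
      if (!is.null(member1$pretrain_log)) {
        cbind(phase = "pretrain", member1$pretrain_log[, c("epoch", "recon_error")],
              layer = member1$pretrain_log$layer)
      },
      if (!is.null(member1$finetune_log)) {
        data.frame(phase = "finetune", epoch = member1$finetune_log$epoch,
                   recon_error = member1$finetune_log$loss, layer = NA)
      })
    paths$training_log <- fp("training_log.csv")
    utils::write.csv(logs, paths$training_log, row.names = FALSE)
    attr(predictions, "models") <- NULL
  }
  paths$predictions <- fp("predictions.csv")
  write_report(as.data.frame(predictions), paths$predictions)

  ## 6. confidence limits
  pipe_log(config, "info", "confidence limits (N = %d, alpha = %s)",
           config$n_cl, format(config$alpha))
  cls <- run_stage("cl", cohort_cl(predictions, config$n_cl, config$alpha,
                                   seed = derive_seed(config$seed, 5L)))
  clrep <- cl_report(cls)
  paths$cl_report <- fp("cl_report.csv")
  write_report(clrep, paths$cl_report)
  paths$cl_summary <- fp("cl_summary.csv")
  write_report(attr(clrep, "summary"), paths$cl_summary)

  ## 7. normality report
  pipe_log(config, "info", "normality and independence suite")
  norm <- run_stage("normality", cohort_normality_report(cls, alpha = 0.05))
  paths$normality <- fp("normality_report.csv")
  write_report(norm$summary, paths$normality)

  ## 8. evaluation
  pipe_log(config, "info", "accuracy evaluation")
  eval_tbl <- run_stage("evaluate", {
    s <- error_summary(predictions$sbp_est, predictions$ref_sbp)
    d <- error_summary(predictions$dbp_est, predictions$ref_dbp)
    data.frame(
      arm = c("SBP", "DBP"),
      me = c(s$me, d$me), sde = c(s$sde, d$sde), mae = c(s$mae, d$mae),
      p5 = 100 * c(s$pct_within[["5"]], d$pct_within[["5"]]),
      p10 = 100 * c(s$pct_within[["10"]], d$pct_within[["10"]]),
      p15 = 100 * c(s$pct_within[["15"]], d$pct_within[["15"]]),
      aami = c(aami_pass(s), aami_pass(d)),
      bhs = c(bhs_grade_summary(s), bhs_grade_summary(d)),
      stringsAsFactors = FALSE)
  })
  paths$evaluation <- fp("evaluation.csv")
  write_report(eval_tbl, paths$evaluation)

  pipe_log(config, "info", "done: %d report files in %s",
           length(paths), config$output_dir)
  invisible(list(cohort = cohort, split = halves, predictions = predictions,
                 cl = cls, normality = norm, evaluation = eval_tbl,
                 paths = paths))
}
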