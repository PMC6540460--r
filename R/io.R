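# File formats: the measurement CSV schema and the YAML run configuration.

measurement_schema <- function(n_features = 11L) {
  c("subject_id", "meas_idx", bp_feature_names(n_features),
    "ref_sbp", "ref_dbp")
}

#' Write a measurement table to CSV
#'
#' Columns: `subject_id`, `meas_idx`, the feature columns, `ref_sbp`,
#' `ref_dbp`.
#'
#' @param records measurement `data.frame`.
#' @param path output file.
#' @export
write_measurements <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a measurement CSV
#'
#' Expects the header `subject_id, meas_idx, <features...>, ref_sbp,
#' ref_dbp`.  Validation failures report the offending column and row.
#'
#' @param path CSV file path.
#' @param n_measurements optionally enforce that every subject has exactly
#'   this many rows; by default all subjects must simply agree.
#' @return a validated measurement `data.frame`.
#' @export
read_measurements <- function(path, n_measurements = NULL) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_fixed <- c("subject_id", "meas_idx", "ref_sbp", "ref_dbp")
  miss <- setdiff(need_fixed, colnames(df))
  if (length(miss) > 0L) {
    stop_validation(paste0("measurement file missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  fcols <- feature_columns(df)
  if (length(fcols) < 1L) {
    stop_validation("measurement file has no feature columns")
  }
  for (cn in c("meas_idx", fcols, "ref_sbp", "ref_dbp")) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1] %||% 1L
      stop_validation(sprintf("non-numeric value in column `%s` (row %d)",
                              cn, bad))
    }
    if (any(!is.finite(v))) {
      stop_validation(sprintf("missing/non-finite value in column `%s` (row %d)",
                              cn, which(!is.finite(v))[1]))
    }
  }
  bad_bp <- which(!(df$ref_sbp > df$ref_dbp & df$ref_dbp > 0))
  if (length(bad_bp) > 0L) {
    stop_validation(sprintf(
      "reference pressures must satisfy ref_sbp > ref_dbp > 0 (row %d)",
      bad_bp[1]))
  }
  counts <- table(df$subject_id)
  expected <- n_measurements %||% as.integer(counts[1])
  off <- names(counts)[counts != expected]
  if (length(off) > 0L) {
    stop_validation(sprintf(
      "subject `%s` has %d rows; expected %d measurements per subject",
      off[1], counts[[off[1]]], expected))
  }
  df
}

#' Full pipeline run configuration
#'
#' Bundles the cohort model, the training recipe and the bootstrap settings
#' (artificial replicates per feature `n_features_boot`, confidence-limit
#' replications `n_cl`, inner resample size, tail probability) with the
#' split size, output directory and log level.  Serializable to a single
#' YAML file.
#'
#' @param cohort a [cohort_config()].
#' @param train a [train_config()].
#' @param n_train_subjects training-subject count for the split.
#' @param n_features_boot artificial samples per original feature.
#' @param n_cl bootstrap replications for confidence limits.
#' @param n_inner inner resample size for mean-mode augmentation.
#' @param alpha per-tail probability of the confidence limits.
#' @param augment_mode `"draw"` or `"mean"` (see [augment_cohort()]).
#' @param seed root seed of the run.
#' @param output_dir where [run_pipeline()] writes its artifacts.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return object of class `bp_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       train = train_config(),
                       n_train_subjects = 60L,
                       n_features_boot = 100L, n_cl = 1000L,
                       n_inner = 5L, alpha = 0.025,
                       augment_mode = "draw",
                       seed = 1L, output_dir = "oscibp-run",
                       log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  cfg <- list(cohort = cohort, train = train,
              n_train_subjects = as.integer(n_train_subjects),
              n_features_boot = as.integer(n_features_boot),
              n_cl = as.integer(n_cl), n_inner = as.integer(n_inner),
              alpha = alpha, augment_mode = augment_mode,
              seed = seed, output_dir = output_dir, log_level = log_level)
  class(cfg) <- "bp_run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  validate_cohort_config(cfg$cohort)
  validate_train_config(cfg$train)
  chk <- function(ok, field, why) {
    if (!ok) stop_validation(sprintf("invalid run config: `%s` %s", field, why))
  }
  chk(is_count(cfg$n_train_subjects, 1L) &&
        cfg$n_train_subjects < cfg$cohort$n_subjects,
      "n_train_subjects", "must be in [1, n_subjects)")
  chk(is_count(cfg$n_features_boot, 1L), "n_features_boot",
      "must be a positive integer")
  chk(is_count(cfg$n_cl, 2L), "n_cl", "must be an integer >= 2")
  chk(is_count(cfg$n_inner, 1L), "n_inner", "must be a positive integer")
  chk(is_number(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 0.5, "alpha",
      "must be in (0, 0.5)")
  chk(cfg$augment_mode %in% c("draw", "mean"), "augment_mode",
      'must be "draw" or "mean"')
  chk(cfg$log_level %in% c("quiet", "info", "debug"), "log_level",
      'must be "quiet", "info" or "debug"')
  invisible(cfg)
}

#' Read / write the run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  ser <- unclass(config)
  ser$cohort <- unclass(ser$cohort)
  ser$cohort$feature_loadings <- list(
    rownames = rownames(config$cohort$feature_loadings),
    sbp = unname(config$cohort$feature_loadings[, 1]),
    dbp = unname(config$cohort$feature_loadings[, 2]))
  ser$train <- unclass(ser$train)
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  raw <- yaml::read_yaml(path)
  fl <- raw$cohort$feature_loadings
  raw$cohort$feature_loadings <- if (!is.null(fl)) {
    m <- cbind(sbp = as.numeric(fl$sbp), dbp = as.numeric(fl$dbp))
    rownames(m) <- fl$rownames
    m
  }
  cohort <- do.call(cohort_config, raw$cohort)
  train_args <- raw$train
  train <- do.call(train_config, train_args)
  rest <- raw[setdiff(names(raw), c("cohort", "train"))]
  do.call(run_config, c(list(cohort = cohort, train = train), rest))
}
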