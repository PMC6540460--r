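# Synthetic cohort generator: study-shaped measurement tables with known
# ground truth, so every downstream stage is testable without clinical data.

#' Canonical oscillometric feature names
#'
#' The eight named envelope features (mean arterial pressure ratio, amplitude
#' ratios, envelope slopes, sigma terms, MAP location) plus three unnamed
#' extra features `F9`--`F11` used to fill the 11-wide input vector.
#'
#' @export
bp_feature_names <- function(n_features = 11L) {
  base <- c("MAP", "AR", "AE", "EL", "MA", "SIG1", "SIG2", "MAPL",
            "F9", "F10", "F11")
  if (n_features == length(base)) return(base)
  if (n_features < length(base)) return(base[seq_len(n_features)])
  c(base, paste0("F", seq(length(base) + 1L, n_features)))
}

# Loadings of each feature on standardized (SBP_true, DBP_true).  The pattern
# mixes SBP-dominant, DBP-dominant and mixed-sign features; with per-feature
# noise sd 0.45 (same standardized units) ordinary least squares on all 11
# features recovers the true pressures with residual sd close to 3 mmHg.
feature_loadings_z <- function(n_features = 11L) {
  base <- rbind(
    MAP  = c(0.33,  0.67),
    AR   = c(0.80,  0.20),
    AE   = c(0.90,  0.10),
    EL   = c(0.20,  0.80),
    MA   = c(0.70,  0.30),
    SIG1 = c(0.60, -0.40),
    SIG2 = c(-0.30, 0.60),
    MAPL = c(0.50,  0.50),
    F9   = c(1.00,  0.00),
    F10  = c(0.00,  1.00),
    F11  = c(0.40, -0.60)
  )
  idx <- rep_len(seq_len(nrow(base)), n_features)
  out <- base[idx, , drop = FALSE]
  rownames(out) <- bp_feature_names(n_features)
  out
}

#' Default feature loadings on the true pressures
#'
#' Linear coefficients of each synthetic feature on the subject-level true
#' `(SBP, DBP)` in mmHg.  Defaults are the standardized loading pattern of
#' [feature_loadings_z()] divided by the population standard deviations, so
#' the feature/pressure association strength is independent of the chosen
#' population spread.
#'
#' @param n_features number of features (default 11).
#' @param pop_sbp_sd,pop_dbp_sd population standard deviations (mmHg) used to
#'   scale the standardized loadings.
#' @return an `n_features x 2` matrix with columns `sbp`, `dbp`.
#' @export
default_feature_loadings <- function(n_features = 11L, pop_sbp_sd = 13,
                                     pop_dbp_sd = 9) {
  z <- feature_loadings_z(n_features)
  out <- cbind(sbp = z[, 1] / pop_sbp_sd, dbp = z[, 2] / pop_dbp_sd)
  rownames(out) <- rownames(z)
  out
}

#' Configuration of a synthetic cohort
#'
#' Describes the population and measurement model of a simulated study
#' cohort: `n_subjects` subjects, each measured `n_measurements` times, every
#' measurement carrying an `n_features`-long oscillometric feature vector and
#' auscultatory reference SBP/DBP in mmHg.
#'
#' Subject-level true pressures are bivariate normal
#' (`pop_sbp_mean`, `pop_sbp_sd`; `pop_dbp_mean`, `pop_dbp_sd`; correlation
#' `pop_bp_cor`).  Each measurement's reference pressure fluctuates around
#' the subject truth with total standard deviation `within_subject_sd_*`;
#' part of that total is contributed by averaging two simulated observers
#' with independent reading noise of sd `observer_sd`.  Features are linear
#' in the true pressures plus Gaussian noise.
#'
#' @param n_subjects,n_measurements,n_features cohort shape
#'   (defaults 85, 5, 11 — the study shape).
#' @param pop_sbp_mean,pop_sbp_sd,pop_dbp_mean,pop_dbp_sd population
#'   moments of the true pressures, mmHg.
#' @param pop_bp_cor correlation between true SBP and DBP.
#' @param within_subject_sd_sbp,within_subject_sd_dbp total per-measurement
#'   fluctuation of the reference pressures around the subject truth, mmHg.
#' @param observer_sd reading noise sd of each of the two simulated
#'   observers, mmHg; their average is part of the within-subject total.
#' @param feature_loadings `n_features x 2` coefficient matrix on the true
#'   `(SBP, DBP)`; default [default_feature_loadings()].
#' @param feature_noise_sd per-feature Gaussian noise sd (scalar or
#'   `n_features` vector).
#' @param seed integer root seed; the generator is fully deterministic
#'   given the configuration.
#' @return an object of class `bp_cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 85L, n_measurements = 5L,
                          n_features = 11L,
                          pop_sbp_mean = 112, pop_sbp_sd = 13,
                          pop_dbp_mean = 66.5, pop_dbp_sd = 9,
                          pop_bp_cor = 0.7,
                          within_subject_sd_sbp = 3.4,
                          within_subject_sd_dbp = 3.6,
                          observer_sd = 1,
                          feature_loadings = NULL,
                          feature_noise_sd = 0.45,
                          seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, n_measurements = n_measurements,
    n_features = n_features,
    pop_sbp_mean = pop_sbp_mean, pop_sbp_sd = pop_sbp_sd,
    pop_dbp_mean = pop_dbp_mean, pop_dbp_sd = pop_dbp_sd,
    pop_bp_cor = pop_bp_cor,
    within_subject_sd_sbp = within_subject_sd_sbp,
    within_subject_sd_dbp = within_subject_sd_dbp,
    observer_sd = observer_sd,
    feature_loadings = feature_loadings %||%
      default_feature_loadings(n_features, pop_sbp_sd, pop_dbp_sd),
    feature_noise_sd = rep_len(feature_noise_sd, n_features),
    seed = seed
  )
  class(cfg) <- "bp_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop_validation(sprintf("invalid cohort config: `%s` %s", field, why))
  }
  chk(is_count(cfg$n_subjects, 1L), "n_subjects", "must be a positive integer")
  chk(is_count(cfg$n_measurements, 2L), "n_measurements", "must be an integer >= 2")
  chk(is_count(cfg$n_features, 1L), "n_features", "must be a positive integer")
  for (f in c("pop_sbp_sd", "pop_dbp_sd")) {
    chk(is_number(cfg[[f]]) && cfg[[f]] > 0, f, "must be > 0")
  }
  for (f in c("within_subject_sd_sbp", "within_subject_sd_dbp", "observer_sd")) {
    chk(is_number(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  }
  chk(is_number(cfg$pop_bp_cor) && abs(cfg$pop_bp_cor) < 1, "pop_bp_cor",
      "must be in (-1, 1)")
  chk(is_number(cfg$pop_sbp_mean) && cfg$pop_sbp_mean > 0, "pop_sbp_mean",
      "must be > 0")
  chk(is_number(cfg$pop_dbp_mean) && cfg$pop_dbp_mean > 0, "pop_dbp_mean",
      "must be > 0")
  chk(is.matrix(cfg$feature_loadings) &&
        nrow(cfg$feature_loadings) == cfg$n_features &&
        ncol(cfg$feature_loadings) == 2L &&
        all(is.finite(cfg$feature_loadings)),
      "feature_loadings", "must be a finite n_features x 2 matrix")
  chk(is.numeric(cfg$feature_noise_sd) &&
        length(cfg$feature_noise_sd) == cfg$n_features &&
        all(is.finite(cfg$feature_noise_sd)) && all(cfg$feature_noise_sd >= 0),
      "feature_noise_sd", "must be non-negative, length n_features")
  chk(is_number(cfg$seed), "seed", "must be a single number")
  invisible(cfg)
}

#' @export
print.bp_cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic BP cohort config: %d subjects x %d measurements, %d features\n",
    x$n_subjects, x$n_measurements, x$n_features))
  cat(sprintf("  SBP ~ N(%.1f, %.1f^2), DBP ~ N(%.1f, %.1f^2), cor %.2f [mmHg]\n",
              x$pop_sbp_mean, x$pop_sbp_sd, x$pop_dbp_mean, x$pop_dbp_sd,
              x$pop_bp_cor))
  cat(sprintf("  within-subject sd: SBP %.2f, DBP %.2f; seed %s\n",
              x$within_subject_sd_sbp, x$within_subject_sd_dbp,
              format(x$seed)))
  invisible(x)
}

# Split the total within-subject sd into a physiological fluctuation part and
# the two-observer averaging part (observer average contributes sd/sqrt(2)).
# The observer part is capped so the total always equals `within_sd`.
noise_decomposition <- function(within_sd, observer_sd) {
  obs_eff <- min(observer_sd, sqrt(2) * within_sd)
  fluct <- sqrt(max(within_sd^2 - obs_eff^2 / 2, 0))
  list(fluct = fluct, observer = obs_eff)
}

#' Generate a synthetic measurement cohort
#'
#' Draws a cohort of subjects with bivariate-normal true pressures, simulates
#' `n_measurements` auscultatory reference readings per subject (subject
#' truth + physiological fluctuation, read by two averaged observers) and an
#' oscillometric feature vector per measurement (linear in the true
#' pressures plus Gaussian noise).  Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `bp_cohort` with columns `subject_id`,
#'   `meas_idx`, the feature columns, `ref_sbp`, `ref_dbp`.  The subject-level
#'   truth table is attached as `attr(, "truth")` and the generating
#'   configuration as `attr(, "config")`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' head(coh)
#' attr(coh, "truth")
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "bp_cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  validate_cohort_config(config)
  B <- config$n_subjects
  n <- config$n_measurements
  p <- config$n_features
  with_seed(config$seed, {
    ## subject-level truth, bivariate normal via Cholesky
    z1 <- rnorm(B); z2 <- rnorm(B)
    rho <- config$pop_bp_cor
    sbp_true <- config$pop_sbp_mean + config$pop_sbp_sd * z1
    dbp_true <- config$pop_dbp_mean +
      config$pop_dbp_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    ## physiology requires a positive pulse pressure; redraw the (very rare)
    ## degenerate truth pairs deterministically
    bad <- which(sbp_true - dbp_true < 5)
    guard <- 0L
    while (length(bad) > 0L && guard < 100L) {
      z1b <- rnorm(length(bad)); z2b <- rnorm(length(bad))
      sbp_true[bad] <- config$pop_sbp_mean + config$pop_sbp_sd * z1b
      dbp_true[bad] <- config$pop_dbp_mean +
        config$pop_dbp_sd * (rho * z1b + sqrt(1 - rho^2) * z2b)
      bad <- bad[sbp_true[bad] - dbp_true[bad] < 5]
      guard <- guard + 1L
    }

    dec_s <- noise_decomposition(config$within_subject_sd_sbp, config$observer_sd)
    dec_d <- noise_decomposition(config$within_subject_sd_dbp, config$observer_sd)
    m <- B * n
    draw_ref <- function(truth_rep, dec) {
      phys <- truth_rep + rnorm(m, 0, dec$fluct)
      phys + (rnorm(m, 0, dec$observer) + rnorm(m, 0, dec$observer)) / 2
    }
    sbp_rep <- rep(sbp_true, each = n)
    dbp_rep <- rep(dbp_true, each = n)
    ref_sbp <- draw_ref(sbp_rep, dec_s)
    ref_dbp <- draw_ref(dbp_rep, dec_d)
    ## rare measurement-noise inversions: redraw that row's noise
    bad <- which(ref_sbp - ref_dbp < 1)
    guard <- 0L
    while (length(bad) > 0L && guard < 100L) {
      ref_sbp[bad] <- draw_ref(sbp_rep[bad], dec_s)[seq_along(bad)]
      ref_dbp[bad] <- draw_ref(dbp_rep[bad], dec_d)[seq_along(bad)]
      bad <- bad[ref_sbp[bad] - ref_dbp[bad] < 1]
      guard <- guard + 1L
    }

    signal <- cbind(sbp_rep, dbp_rep) %*% t(config$feature_loadings)
    noise <- matrix(rnorm(m * p), m, p) %*% diag(config$feature_noise_sd, p)
    features <- signal + noise
    colnames(features) <- rownames(config$feature_loadings) %||%
      bp_feature_names(p)

    ids <- sprintf("S%03d", seq_len(B))
    out <- data.frame(
      subject_id = rep(ids, each = n),
      meas_idx = rep(seq_len(n), times = B),
      features,
      ref_sbp = ref_sbp,
      ref_dbp = ref_dbp,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- data.frame(
      subject_id = ids, sbp_true = sbp_true, dbp_true = dbp_true,
      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("bp_cohort", "data.frame")
    out
  })
}

#' Subject-disjoint train/test split
#'
#' Splits a measurement table so that the first `n_train_subjects` subjects
#' (in order of appearance) form the training set and the remainder the test
#' set; all measurements of a subject fall on the same side.
#'
#' @param records a measurement `data.frame` (e.g. from [generate_cohort()]
#'   or [read_measurements()]).
#' @param n_train_subjects number of training subjects; must be strictly
#'   between 0 and the number of subjects.
#' @return `list(train = , test = )` of measurement tables.
#' @export
split_cohort <- function(records, n_train_subjects) {
  ids <- unique(records$subject_id)
  if (!is_count(n_train_subjects, 1L) || n_train_subjects >= length(ids)) {
    stop_validation(sprintf(
      "n_train_subjects must be an integer in [1, %d); got %s",
      length(ids), format(n_train_subjects)))
  }
  train_ids <- ids[seq_len(n_train_subjects)]
  take <- records$subject_id %in% train_ids
  list(train = records[take, , drop = FALSE],
       test = records[!take, , drop = FALSE])
}

feature_columns <- function(records) {
  setdiff(colnames(records), c("subject_id", "meas_idx", "ref_sbp", "ref_dbp"))
}
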