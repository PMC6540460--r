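# Per-subject percentile-bootstrap confidence limits for the BP estimates:
# fit a Gaussian to the n (default 5) per-subject estimates, draw an n x N
# replicate matrix, take column means, sort, and read off percentile limits.

#' Parametric-bootstrap replicate means for one subject
#'
#' Fits `(mu_hat, sigma_hat)` to the subject's estimates, draws an
#' `n x n_rep` matrix `mu_hat + sigma_hat * Z`, takes column means and sorts
#' them ascending.  Both the generation-order and sorted vectors are kept
#' (the unsorted stream is what independence tests must see).
#'
#' @param estimates the subject's per-measurement BP estimates (mmHg),
#'   length >= 2 (default design: 5).
#' @param n_rep number of bootstrap replications N (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_means`: `values` (generation order),
#'   `sorted`, `mu_hat`, `sigma_hat`, `n`, `n_rep`, `seed`.
#' @export
bootstrap_means <- function(estimates, n_rep = 1000L, seed = 1L) {
  if (!is.numeric(estimates) || length(estimates) < 2L) {
    stop_validation("bootstrap_means needs at least 2 estimates")
  }
  if (any(!is.finite(estimates))) {
    stop_validation("estimates contain non-finite values")
  }
  if (!is_count(n_rep, 2L)) stop_validation("n_rep must be an integer >= 2")
  fit <- gaussian_fit(estimates)
  n <- fit$n
  values <- with_seed(seed, {
    M <- matrix(fit$mean + fit$sd * rnorm(n * n_rep), n, n_rep)
    colMeans(M)
  })
  structure(
    list(values = values, sorted = sort(values),
         mu_hat = fit$mean, sigma_hat = fit$sd,
         n = n, n_rep = as.integer(n_rep), seed = as.integer(seed)),
    class = "bootstrap_means")
}

#' @export
print.bootstrap_means <- function(x, ...) {
  cat(sprintf(
    "Bootstrap means: N = %d replicates of the mean of n = %d draws\n",
    x$n_rep, x$n))
  cat(sprintf("  fit: mu %s, sigma %s; replicate range [%s, %s]\n",
              fmt_num(x$mu_hat), fmt_num(x$sigma_hat),
              fmt_num(min(x$sorted)), fmt_num(max(x$sorted))))
  invisible(x)
}

#' Percentile interval of sorted bootstrap means
#'
#' The Efron percentile rule with 1-based order-statistic indices
#' `ceiling(alpha * N)` and `ceiling((1 - alpha) * N)`.
#'
#' @param bm a [bootstrap_means()] object (or any list with a `sorted`
#'   numeric field).
#' @param alpha per-tail probability, in (0, 0.5).
#' @return named vector `c(lower = , upper = )` in mmHg.
#' @examples
#' bm <- bootstrap_means(c(110, 112, 113, 115, 111), seed = 42)
#' percentile_interval(bm, 0.025)
#' @export
percentile_interval <- function(bm, alpha = 0.025) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 0.5) {
    stop_validation("alpha must be in (0, 0.5)")
  }
  s <- bm$sorted
  N <- length(s)
  lo <- max(1L, ceiling(alpha * N))
  hi <- ceiling((1 - alpha) * N)
  c(lower = s[lo], upper = s[hi])
}

#' Confidence limits for one subject
#'
#' Runs the bootstrap-mean procedure and the percentile rule independently
#' on the subject's SBP and DBP estimate streams (separate derived seeds, so
#' the two arms are statistically independent and one arm's results are
#' unchanged by edits to the other).
#'
#' @param subject_id identifier carried through to the report.
#' @param sbp_estimates,dbp_estimates per-measurement estimates, mmHg.
#' @param n_rep bootstrap replications N (default 1000).
#' @param alpha per-tail probability (default 0.025, i.e. 95% limits).
#' @param seed root seed; SBP and DBP use sub-streams derived from it.
#' @return object of class `bp_cl`: `sbp_lower`, `sbp_upper`, `dbp_lower`,
#'   `dbp_upper`, widths, and the two [bootstrap_means()] objects (`$sbp`,
#'   `$dbp`).
#' @export
estimate_cl <- function(subject_id, sbp_estimates, dbp_estimates,
                        n_rep = 1000L, alpha = 0.025, seed = 1L) {
  bm_s <- bootstrap_means(sbp_estimates, n_rep, derive_seed(seed, 1L))
  bm_d <- bootstrap_means(dbp_estimates, n_rep, derive_seed(seed, 2L))
  ci_s <- percentile_interval(bm_s, alpha)
  ci_d <- percentile_interval(bm_d, alpha)
  structure(
    list(subject_id = subject_id, alpha = alpha,
         sbp_lower = ci_s[["lower"]], sbp_upper = ci_s[["upper"]],
         dbp_lower = ci_d[["lower"]], dbp_upper = ci_d[["upper"]],
         sbp_width = ci_s[["upper"]] - ci_s[["lower"]],
         dbp_width = ci_d[["upper"]] - ci_d[["lower"]],
         sbp = bm_s, dbp = bm_d),
    class = "bp_cl")
}

#' @export
print.bp_cl <- function(x, ...) {
  cat(sprintf(
    "Subject %s %d%% confidence limits: SBP [%.1f, %.1f], DBP [%.1f, %.1f] mmHg\n",
    format(x$subject_id), round(100 * (1 - 2 * x$alpha)),
    x$sbp_lower, x$sbp_upper, x$dbp_lower, x$dbp_upper))
  invisible(x)
}

#' Confidence limits for every subject of a prediction table
#'
#' @param predictions a `data.frame` with columns `subject_id`, `sbp_est`,
#'   `dbp_est` (one row per measurement).
#' @param n_rep,alpha,seed as in [estimate_cl()]; per-subject seeds are
#'   derived from `seed` and a stable hash of the subject id, so one
#'   subject's limits do not depend on the table's ordering.
#' @return a list of `bp_cl` objects, one per subject, named by subject id.
#' @export
cohort_cl <- function(predictions, n_rep = 1000L, alpha = 0.025, seed = 1L) {
  need <- c("subject_id", "sbp_est", "dbp_est")
  miss <- setdiff(need, colnames(predictions))
  if (length(miss) > 0L) {
    stop_validation(paste0("predictions missing column(s): ",
                           paste(miss, collapse = ", ")))
  }
  ids <- unique(predictions$subject_id)
  out <- lapply(seq_along(ids), function(i) {
    rows <- predictions[predictions$subject_id == ids[i], , drop = FALSE]
    estimate_cl(ids[i], rows$sbp_est, rows$dbp_est, n_rep, alpha,
                derive_seed(seed, 100L, id_key(ids[i])))
  })
  names(out) <- ids
  out
}

#' Tabulate per-subject confidence limits
#'
#' One row per subject with centre estimates, lower/upper limits and widths
#' for both arms, plus a cohort summary attribute (mean and across-subject
#' sd of each column — the usual comparison-table layout).
#'
#' @param cl_results list of `bp_cl` objects from [cohort_cl()].
#' @return `data.frame`, one row per subject; `attr(, "summary")` holds the
#'   cohort means and sds, including the mean CL widths.
#' @export
cl_report <- function(cl_results) {
  if (length(cl_results) == 0L) stop_validation("empty confidence-limit set")
  rows <- lapply(cl_results, function(cl) {
    data.frame(
      subject_id = cl$subject_id,
      sbp_est = cl$sbp$mu_hat, dbp_est = cl$dbp$mu_hat,
      sbp_lower = cl$sbp_lower, sbp_upper = cl$sbp_upper,
      sbp_width = cl$sbp_width,
      dbp_lower = cl$dbp_lower, dbp_upper = cl$dbp_upper,
      dbp_width = cl$dbp_width,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- out[, -1, drop = FALSE]
  attr(out, "summary") <- data.frame(
    column = colnames(num),
    mean = vapply(num, mean, numeric(1)),
    sd = vapply(num, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
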