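# Parametric bootstrap: Gaussian fit of a small sample, artificial replicate
# generation, and bias / standard-error / convergence diagnostics.

#' Fit a Gaussian to a small sample
#'
#' The parametric-bootstrap generating distribution: the sample mean and the
#' n-1 denominator standard deviation of the observed values.
#'
#' @param sample numeric vector, length >= 2.
#' @return object of class `gaussian_fit` with fields `mean`, `sd`, `n`.
#' @examples
#' gaussian_fit(c(1, 2, 3, 4, 5))
#' @export
gaussian_fit <- function(sample) {
  if (!is.numeric(sample) || length(sample) < 2L) {
    stop_validation("gaussian_fit needs at least 2 numeric values")
  }
  if (any(!is.finite(sample))) stop_validation("sample contains non-finite values")
  structure(
    list(mean = mean(sample), sd = stats::sd(sample), n = length(sample)),
    class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: mean %s, sd %s (n = %d)\n",
              fmt_num(x$mean), fmt_num(x$sd), x$n))
  invisible(x)
}

#' Construct a Gaussian fit from known statistics
#'
#' For workflows that start from printed or previously computed summary
#' statistics rather than raw measurements.
#'
#' @param mean,sd the fitted mean and (n-1) standard deviation.
#' @param n the size of the sample they were fitted from.
#' @return a `gaussian_fit` object.
#' @export
as_gaussian_fit <- function(mean, sd, n) {
  if (!is_number(mean) || !is_number(sd) || !is_count(n, 2L)) {
    stop_validation("as_gaussian_fit needs numeric mean/sd and integer n >= 2")
  }
  if (sd < 0) stop_validation("sd must be >= 0")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "gaussian_fit")
}

#' Draw a parametric-bootstrap artificial sample
#'
#' Generates `n_rep` artificial replicate values from a fitted Gaussian.
#' Each replicate is the mean of `n_inner` independent
#' `Normal(fit$mean, fit$sd^2)` draws; `n_inner = 1` gives raw Gaussian
#' draws (the default mode used for feature augmentation), `n_inner = 5`
#' reproduces the 5-measurement resample mean used for confidence limits.
#'
#' @param fit a [gaussian_fit()].
#' @param n_inner size of each inner resample (>= 1).
#' @param n_rep number of artificial replicates N (>= 1).
#' @param seed integer seed; the sample is reproducible from
#'   `(fit, n_inner, n_rep, seed)`.
#' @return object of class `artificial_sample` with fields `values`
#'   (length `n_rep`, generation order), `source`, `n_inner`, `seed`.
#' @export
artificial_sample <- function(fit, n_inner = 1L, n_rep, seed = 1L) {
  if (!inherits(fit, "gaussian_fit")) stop_validation("fit must be a gaussian_fit")
  if (!is.finite(fit$sd) || fit$sd < 0) stop_validation("fit sd must be >= 0")
  if (!is_count(n_inner, 1L)) stop_validation("n_inner must be a positive integer")
  if (!is_count(n_rep, 1L)) stop_validation("n_rep must be a positive integer")
  values <- with_seed(seed, {
    draws <- matrix(rnorm(n_inner * n_rep, fit$mean, fit$sd), n_inner, n_rep)
    colMeans(draws)
  })
  structure(
    list(values = values, source = fit, n_inner = as.integer(n_inner),
         n_rep = as.integer(n_rep), seed = as.integer(seed)),
    class = "artificial_sample")
}

#' @export
print.artificial_sample <- function(x, ...) {
  cat(sprintf(
    "Artificial sample: N = %d replicates (each a mean of %d draws)\n",
    x$n_rep, x$n_inner))
  cat(sprintf("  source: mean %s, sd %s (n = %d); seed %d\n",
              fmt_num(x$source$mean), fmt_num(x$source$sd), x$source$n, x$seed))
  invisible(x)
}

#' Bootstrap bias of an artificial sample
#'
#' The mean of the artificial replicates minus the source fit mean: the
#' prediction error of the bootstrap estimator of the sample mean.
#'
#' @param art an [artificial_sample()].
#' @return bias (same units as the sample).
#' @export
bootstrap_bias <- function(art) {
  if (!inherits(art, "artificial_sample")) {
    stop_validation("art must be an artificial_sample")
  }
  mean(art$values) - art$source$mean
}

#' Bootstrap standard error of an artificial sample
#'
#' The n-1 denominator standard deviation of the artificial replicates: the
#' parametric-bootstrap standard error of the sample mean.
#'
#' @param art an [artificial_sample()] with at least 2 replicates.
#' @return standard error (same units as the sample).
#' @export
bootstrap_se <- function(art) {
  if (!inherits(art, "artificial_sample")) {
    stop_validation("art must be an artificial_sample")
  }
  if (art$n_rep < 2L) stop_validation("bootstrap_se needs N >= 2 replicates")
  stats::sd(art$values)
}

#' One-row bootstrap diagnostic summary
#'
#' Mirrors the per-feature diagnostic layout used when validating artificial
#' against original features: original fit mean and sd, artificial mean and
#' sd, percentile confidence limits of the artificial values, bias and the
#' two standard errors.
#'
#' @param art an [artificial_sample()].
#' @param alpha per-tail probability for the percentile limits.
#' @return a one-row `data.frame` with columns `theta_hat`, `theta_star`,
#'   `cl_lower`, `cl_upper`, `bias`, `se_hat`, `se_star`.
#' @export
bootstrap_diagnostics <- function(art, alpha = 0.025) {
  sorted <- sort(art$values)
  N <- length(sorted)
  lo <- sorted[max(1L, ceiling(alpha * N))]
  hi <- sorted[ceiling((1 - alpha) * N)]
  data.frame(
    theta_hat = art$source$mean,
    theta_star = mean(art$values),
    cl_lower = lo,
    cl_upper = hi,
    bias = bootstrap_bias(art),
    se_hat = art$source$sd,
    se_star = if (N >= 2L) bootstrap_se(art) else NA_real_)
}

#' Convergence of the bootstrap distribution of the mean
#'
#' For each replicate count in `n_grid`, draws an artificial sample and
#' measures the Kolmogorov-Smirnov sup-distance between the empirical
#' distribution of `sqrt(n_inner) * (theta* - theta_hat)` and its limiting
#' `Normal(0, sd^2)` law.  Distances decrease at the usual `1/sqrt(N)` rate.
#'
#' @param fit a [gaussian_fit()].
#' @param n_inner inner resample size.
#' @param n_grid increasing vector of replicate counts.
#' @param seed root seed (one sub-stream per grid point).
#' @return `data.frame` with columns `n_rep`, `ks_distance`.
#' @export
convergence_check <- function(fit, n_inner = 5L, n_grid = c(100L, 1000L, 10000L),
                              seed = 1L) {
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop_validation("n_grid must be strictly increasing")
  }
  dist <- vapply(seq_along(n_grid), function(i) {
    N <- n_grid[i]
    art <- artificial_sample(fit, n_inner, N, derive_seed(seed, i))
    if (fit$sd == 0) return(0)
    z <- sort(sqrt(n_inner) * (art$values - fit$mean))
    fr <- pnorm(z, 0, fit$sd)
    max(seq_len(N) / N - fr, fr - (seq_len(N) - 1L) / N)
  }, numeric(1))
  data.frame(n_rep = as.integer(n_grid), ks_distance = dist)
}

#' Bootstrap augmentation of a measurement cohort
#'
#' Expands each subject's `n` measurements into `n_art` artificial
#' measurements by fitting a Gaussian per (subject, column) over the original
#' measurements and drawing replicates — features and reference pressures
#' alike.  Seeds are derived per (subject, column) from `seed`, so results do
#' not depend on iteration order.
#'
#' @param records measurement table (features + `ref_sbp`, `ref_dbp`).
#' @param n_art artificial measurements per subject (default 100).
#' @param mode `"draw"` (raw Gaussian draws, default) or `"mean"` (each
#'   artificial value a mean of `n_inner` draws).
#' @param n_inner inner resample size for `mode = "mean"`.
#' @param seed root seed.
#' @return a measurement table of `n_art` rows per subject, same columns as
#'   `records`, with `meas_idx` running `1..n_art`.
#' @export
augment_cohort <- function(records, n_art = 100L, mode = c("draw", "mean"),
                           n_inner = 5L, seed = 1L) {
  mode <- match.arg(mode)
  inner <- if (mode == "draw") 1L else as.integer(n_inner)
  cols <- c(feature_columns(records), "ref_sbp", "ref_dbp")
  ids <- unique(records$subject_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- records[records$subject_id == ids[i], , drop = FALSE]
    key <- id_key(ids[i])
    art <- lapply(seq_along(cols), function(j) {
      fit <- gaussian_fit(rows[[cols[j]]])
      artificial_sample(fit, inner, n_art, derive_seed(seed, key, j))$values
    })
    names(art) <- cols
    out[[i]] <- data.frame(subject_id = ids[i], meas_idx = seq_len(n_art),
                           art, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject augmentation diagnostics table
#'
#' One diagnostic row per (subject, column): the original fit, artificial
#' summary, percentile limits, bias and standard errors, in the layout used
#' to validate artificial against original features.
#'
#' @inheritParams augment_cohort
#' @param n_art replicates per diagnostic sample (default 100).
#' @param alpha per-tail probability for the limits.
#' @return a `data.frame` with `subject_id`, `column` and the
#'   [bootstrap_diagnostics()] columns.
#' @export
augmentation_diagnostics <- function(records, n_art = 100L, n_inner = 5L,
                                     alpha = 0.025, seed = 1L) {
  cols <- c("ref_sbp", "ref_dbp", feature_columns(records))
  ids <- unique(records$subject_id)
  out <- vector("list", length(ids) * length(cols))
  k <- 0L
  for (i in seq_along(ids)) {
    rows <- records[records$subject_id == ids[i], , drop = FALSE]
    key <- id_key(ids[i])
    for (j in seq_along(cols)) {
      fit <- gaussian_fit(rows[[cols[j]]])
      art <- artificial_sample(fit, n_inner, n_art, derive_seed(seed, key, j))
      k <- k + 1L
      out[[k]] <- cbind(
        data.frame(subject_id = ids[i], column = cols[j],
                   stringsAsFactors = FALSE),
        bootstrap_diagnostics(art, alpha))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
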