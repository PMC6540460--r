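# Moment-based normality tests (kurtosis/skewness with z-scores), the
# Spearman rank independence test, and the cohort-level report that applies
# them to per-subject bootstrap BP distributions.

central_moment <- function(x, k) mean((x - mean(x))^k)

#' Sample kurtosis (population-moment form)
#'
#' `m4 / m2^2` with central moments using the `n` denominator — the
#' non-excess kurtosis, equal to 3 for a normal population.  Algebraically
#' identical to the raw-moment expansion
#' `(E x^4 - 4 mu E x^3 + 6 mu^2 sigma^2 + 3 mu^4) / sigma^4` with
#' `sigma^2 = m2`.
#'
#' @param x numeric sample, length >= 4, non-degenerate.
#' @return the kurtosis.
#' @examples
#' kurtosis(c(2, 4, 6, 8))  # 1.64
#' @export
kurtosis <- function(x) {
  if (!is.numeric(x) || length(x) < 4L) {
    stop_validation("kurtosis needs at least 4 numeric values")
  }
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop_validation("degenerate sample: all values equal")
  central_moment(x, 4) / m2^2
}

#' Sample skewness (population-moment form)
#'
#' `m3 / m2^(3/2)` with central moments using the `n` denominator; 0 for any
#' exactly symmetric sample.
#'
#' @param x numeric sample, length >= 3, non-degenerate.
#' @return the skewness.
#' @examples
#' skewness(c(0, 0, 1))  # 0.7071
#' @export
skewness <- function(x) {
  if (!is.numeric(x) || length(x) < 3L) {
    stop_validation("skewness needs at least 3 numeric values")
  }
  m2 <- central_moment(x, 2)
  if (m2 == 0) stop_validation("degenerate sample: all values equal")
  central_moment(x, 3) / m2^1.5
}

#' Standard error of the sample kurtosis under normality
#'
#' Exact finite-sample formula
#' `sqrt(24 n (n-1)^2 / ((n-2)(n-3)(n+5)(n+3)))`.
#'
#' @param n sample size, >= 4.
#' @export
se_kurtosis <- function(n) {
  if (!is_count(n, 4L)) stop_validation("se_kurtosis needs integer n >= 4")
  sqrt(24 * n * (n - 1)^2 / ((n - 2) * (n - 3) * (n + 5) * (n + 3)))
}

#' Standard error of the sample skewness under normality
#'
#' Exact finite-sample formula `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))`;
#' approaches `sqrt(6/n)` for large `n`.
#'
#' @param n sample size, >= 3.
#' @export
se_skewness <- function(n) {
  if (!is_count(n, 3L)) stop_validation("se_skewness needs integer n >= 3")
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Joint kurtosis/skewness normality test
#'
#' z-scores the sample kurtosis against its normal-theory null value 3 and
#' the skewness against 0, each divided by its exact finite-sample standard
#' error; either `|z| > qnorm(1 - alpha/2)` rejects the joint null of
#' normality.
#'
#' @param x numeric sample (length >= 4).
#' @param alpha significance level.
#' @return object of class `moment_normality_test`: components `kurtosis`
#'   and `skewness` (each with `statistic`, `se`, `z`, `reject`) and the
#'   joint `reject` flag.
#' @export
moment_normality_test <- function(x, alpha = 0.05) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be in (0, 1)")
  }
  n <- length(x)
  zcrit <- qnorm(1 - alpha / 2)
  one <- function(stat, null, se) {
    z <- (stat - null) / se
    list(statistic = stat, null = null, se = se, z = z,
         reject = abs(z) > zcrit)
  }
  k <- one(kurtosis(x), 3, se_kurtosis(n))
  s <- one(skewness(x), 0, se_skewness(n))
  structure(
    list(kurtosis = k, skewness = s, reject = k$reject || s$reject,
         n = n, alpha = alpha),
    class = "moment_normality_test")
}

#' @export
print.moment_normality_test <- function(x, ...) {
  cat(sprintf("Moment normality test (n = %d, alpha = %s)\n", x$n,
              format(x$alpha)))
  cat(sprintf("  kurtosis %s (se %s, z %s)%s\n",
              fmt_num(x$kurtosis$statistic), fmt_num(x$kurtosis$se),
              fmt_num(x$kurtosis$z), if (x$kurtosis$reject) " *" else ""))
  cat(sprintf("  skewness %s (se %s, z %s)%s\n",
              fmt_num(x$skewness$statistic), fmt_num(x$skewness$se),
              fmt_num(x$skewness$z), if (x$skewness$reject) " *" else ""))
  cat(if (x$reject) "  joint normality REJECTED\n" else "  normality not rejected\n")
  invisible(x)
}

#' Spearman rank independence test
#'
#' Spearman's rank correlation (average ranks for ties) with the asymptotic
#' null distribution `E(r) = 0`, `var(r) = 1/(N-1)`, so
#' `z = r * sqrt(N - 1)`; `|z| > qnorm(1 - alpha/2)` rejects independence.
#'
#' @param x,y numeric vectors of equal length `N >= 3`.
#' @param alpha significance level.
#' @return object of class `rank_test_result`: `r`, `z`, `reject`, `n`.
#' @export
spearman_independence <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length")
  }
  if (length(x) < 3L) stop_validation("need at least 3 paired observations")
  r <- stats::cor(rank(x), rank(y))
  z <- r * sqrt(length(x) - 1)
  structure(
    list(r = r, z = z, reject = abs(z) > qnorm(1 - alpha / 2),
         n = length(x), alpha = alpha),
    class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf(
    "Spearman rank independence test (N = %d): r = %s, z = %s -> %s\n",
    x$n, fmt_num(x$r), fmt_num(x$z),
    if (x$reject) "dependence detected" else "independence not rejected"))
  invisible(x)
}

#' Cohort-level normality and independence report
#'
#' Applies the full verification suite to each subject's bootstrap BP
#' distributions (the unsorted replicate vectors stored in the
#' [estimate_cl()] results): kurtosis, skewness, the KS test against a
#' fitted normal, and the Spearman correlation between the paired SBP and
#' DBP replicate streams.  Summarises each statistic as a cohort mean with
#' across-subject standard deviation, one row for SBP and one for DBP.
#'
#' Subjects whose bootstrap distribution is degenerate (all five estimates
#' identical) cannot be tested; they are excluded and counted.
#'
#' @param cl_results a list of `bp_cl` objects (see [cohort_cl()]).
#' @param alpha significance level for all tests.
#' @return object of class `bp_normality_report`: `$summary` (the mean/sd
#'   table), `$per_subject` (all per-subject statistics),
#'   `$spearman_var_empirical` and `$spearman_var_theoretical` (the two
#'   readings of the variance of `r`), `$n_excluded`.
#' @export
cohort_normality_report <- function(cl_results, alpha = 0.05) {
  if (length(cl_results) == 0L) stop_validation("empty confidence-limit set")
  degenerate <- vapply(cl_results, function(cl) {
    cl$sbp$sigma_hat == 0 || cl$dbp$sigma_hat == 0
  }, logical(1))
  n_excluded <- sum(degenerate)
  if (n_excluded > 0L) {
    message(sprintf(
      "cohort_normality_report: excluded %d degenerate subject(s)", n_excluded))
  }
  use <- cl_results[!degenerate]
  if (length(use) == 0L) stop_validation("all subjects degenerate")

  per <- lapply(use, function(cl) {
    row <- function(arm) {
      bm <- cl[[arm]]
      ks <- ks_test(bm$values, alpha = alpha)
      data.frame(
        subject_id = cl$subject_id, arm = toupper(arm),
        h = ks$h, p = ks$p, ks = ks$ks, cv = ks$cv,
        kurtosis = kurtosis(bm$values), skewness = skewness(bm$values),
        stringsAsFactors = FALSE)
    }
    out <- rbind(row("sbp"), row("dbp"))
    out$corr <- spearman_independence(cl$sbp$values, cl$dbp$values, alpha)$r
    out
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  stat_cols <- c("h", "p", "ks", "cv", "kurtosis", "skewness", "corr")
  summarise_arm <- function(arm) {
    sub <- per[per$arm == arm, stat_cols, drop = FALSE]
    means <- vapply(sub, mean, numeric(1))
    sds <- vapply(sub, stats::sd, numeric(1))
    out <- data.frame(arm = arm, stringsAsFactors = FALSE)
    for (cn in stat_cols) {
      out[[cn]] <- means[[cn]]
      out[[paste0(cn, "_sd")]] <- sds[[cn]]
    }
    out
  }
  summary <- rbind(summarise_arm("SBP"), summarise_arm("DBP"))
  N <- length(use[[1]]$sbp$values)
  r_by_subject <- per$corr[per$arm == "SBP"]
  structure(
    list(summary = summary, per_subject = per,
         spearman_var_empirical = stats::var(r_by_subject),
         spearman_var_theoretical = 1 / (N - 1),
         n_replications = N,
         n_subjects = length(use), n_excluded = n_excluded, alpha = alpha),
    class = "bp_normality_report")
}

#' @export
print.bp_normality_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Bootstrap BP normality report: %d subjects (%d excluded), N = %d, alpha = %s\n",
    x$n_subjects, x$n_excluded, x$n_replications, format(x$alpha)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %s: h %s (%s)  p %s (%s)  ks %s (%s)  cv %s (%s)  kurt %s (%s)  skew %s (%s)  corr %s (%s)\n",
      s$arm[i],
      fmt_num(s$h[i], 2), fmt_num(s$h_sd[i], 2),
      fmt_num(s$p[i], 2), fmt_num(s$p_sd[i], 2),
      fmt_num(s$ks[i], 2), fmt_num(s$ks_sd[i], 2),
      fmt_num(s$cv[i], 2), fmt_num(s$cv_sd[i], 2),
      fmt_num(s$kurtosis[i], 3), fmt_num(s$kurtosis_sd[i], 2),
      fmt_num(s$skewness[i], 2), fmt_num(s$skewness_sd[i], 2),
      fmt_num(s$corr[i], 2), fmt_num(s$corr_sd[i], 2)))
  }
  cat(sprintf("  var(r): empirical %s, theoretical 1/(N-1) = %s\n",
              fmt_num(x$spearman_var_empirical),
              fmt_num(x$spearman_var_theoretical)))
  invisible(x)
}
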