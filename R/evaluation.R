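# Accuracy grading of BP estimates: mean error / SDE (the AAMI SP10
# criteria), absolute-error bands with BHS letter grades, and side-by-side
# comparison tables.

#' Error summary of BP estimates against references
#'
#' Errors are `estimate - reference`.  Reports the mean error (ME), the n-1
#' standard deviation of error (SDE), the mean absolute error (MAE) and the
#' fractions of absolute errors within 5, 10 and 15 mmHg.
#'
#' @param estimates,references numeric vectors of equal length >= 2, mmHg.
#' @return object of class `bp_error_summary`: `me`, `sde`, `mae`,
#'   `pct_within` (named fractions at 5/10/15 mmHg), `n`.
#' @examples
#' error_summary(c(121, 118), c(120, 119))
#' @export
error_summary <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    stop_validation("estimates and references must have equal length")
  }
  if (length(estimates) < 2L) stop_validation("need at least 2 paired values")
  e <- estimates - references
  if (any(!is.finite(e))) stop_validation("non-finite errors")
  structure(
    list(me = mean(e), sde = stats::sd(e), mae = mean(abs(e)),
         pct_within = c(`5` = mean(abs(e) <= 5),
                        `10` = mean(abs(e) <= 10),
                        `15` = mean(abs(e) <= 15)),
         n = length(e)),
    class = "bp_error_summary")
}

#' @export
print.bp_error_summary <- function(x, ...) {
  cat(sprintf("BP error summary (n = %d): ME %.2f, SDE %.2f, MAE %.2f mmHg\n",
              x$n, x$me, x$sde, x$mae))
  cat(sprintf("  within 5/10/15 mmHg: %.1f%% / %.1f%% / %.1f%%\n",
              100 * x$pct_within[["5"]], 100 * x$pct_within[["10"]],
              100 * x$pct_within[["15"]]))
  invisible(x)
}

#' AAMI SP10 pass/fail
#'
#' A BP algorithm passes when `|ME| <= 5` mmHg and `SDE <= 8` mmHg.
#'
#' @param summary a [error_summary()] result, or a list with `me` and `sde`.
#' @return logical flag.
#' @export
aami_pass <- function(summary) {
  if (!is_number(summary$me) || !is_number(summary$sde)) {
    stop_validation("summary must carry numeric me and sde")
  }
  abs(summary$me) <= 5 && summary$sde <= 8
}

bhs_thresholds <- data.frame(
  grade = c("A", "B", "C"),
  p5 = c(60, 50, 40), p10 = c(85, 75, 65), p15 = c(95, 90, 85))

#' BHS letter grade from absolute-error band percentages
#'
#' British Hypertension Society protocol: grade A needs at least 60% of
#' absolute errors within 5 mmHg, 85% within 10 mmHg and 95% within 15
#' mmHg; B needs 50/75/90, C needs 40/65/85; otherwise D.  All three
#' thresholds of a row must be met.
#'
#' @param pct5,pct10,pct15 percentages (0-100) of absolute errors within
#'   5, 10 and 15 mmHg; must be non-decreasing.
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @examples
#' bhs_grade(69.18, 88.71, 97.18)  # "A"
#' @export
bhs_grade <- function(pct5, pct10, pct15) {
  p <- c(pct5, pct10, pct15)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    stop_validation("band percentages must lie in [0, 100]")
  }
  if (is.unsorted(p)) {
    stop_validation("band percentages must be non-decreasing across 5/10/15 mmHg")
  }
  for (i in seq_len(nrow(bhs_thresholds))) {
    t <- bhs_thresholds[i, ]
    if (pct5 >= t$p5 && pct10 >= t$p10 && pct15 >= t$p15) return(t$grade)
  }
  "D"
}

#' @rdname bhs_grade
#' @param summary a [error_summary()]; convenience wrapper converting its
#'   band fractions to percentages.
#' @export
bhs_grade_summary <- function(summary) {
  p <- 100 * summary$pct_within
  bhs_grade(p[["5"]], p[["10"]], p[["15"]])
}

#' Side-by-side method comparison report
#'
#' Assembles the three standard comparison layouts from per-method results:
#' mean error / SDE per arm; absolute-error bands with the BHS grade per
#' arm; and (when confidence limits are supplied) the mean CL width and the
#' mean lower/upper limits with across-subject standard deviations.
#'
#' @param method_results a named list; each element is a list with
#'   components `sbp` and `dbp` (each a [error_summary()]) and optionally
#'   `cl` (a list of `bp_cl` objects from [cohort_cl()]).
#' @return object of class `bp_comparison_report`: data.frames
#'   `$accuracy`, `$bhs`, and `$cl` (NULL, with a warning, when no method
#'   supplied confidence limits).
#' @export
comparison_report <- function(method_results) {
  if (length(method_results) == 0L) stop_validation("no method results supplied")
  if (is.null(names(method_results))) {
    names(method_results) <- paste0("method", seq_along(method_results))
  }
  acc <- do.call(rbind, lapply(names(method_results), function(nm) {
    r <- method_results[[nm]]
    data.frame(method = nm,
               sbp_me = r$sbp$me, sbp_sde = r$sbp$sde, sbp_mae = r$sbp$mae,
               dbp_me = r$dbp$me, dbp_sde = r$dbp$sde, dbp_mae = r$dbp$mae,
               aami_sbp = aami_pass(r$sbp), aami_dbp = aami_pass(r$dbp),
               stringsAsFactors = FALSE)
  }))
  bhs <- do.call(rbind, lapply(names(method_results), function(nm) {
    r <- method_results[[nm]]
    ps <- 100 * r$sbp$pct_within
    pd <- 100 * r$dbp$pct_within
    data.frame(method = nm,
               sbp_p5 = ps[["5"]], sbp_p10 = ps[["10"]], sbp_p15 = ps[["15"]],
               dbp_p5 = pd[["5"]], dbp_p10 = pd[["10"]], dbp_p15 = pd[["15"]],
               grade = paste0(bhs_grade_summary(r$sbp), "/",
                              bhs_grade_summary(r$dbp)),
               stringsAsFactors = FALSE)
  }))
  has_cl <- vapply(method_results, function(r) !is.null(r$cl), logical(1))
  cl <- NULL
  if (!any(has_cl)) {
    warning("no method supplied confidence limits; CL section omitted")
  } else {
    cl <- do.call(rbind, lapply(names(method_results)[has_cl], function(nm) {
      rep <- cl_report(method_results[[nm]]$cl)
      s <- attr(rep, "summary")
      get <- function(col, what) s[s$column == col, what]
      data.frame(method = nm,
                 sbp_ci = get("sbp_width", "mean"),
                 sbp_ci_sd = get("sbp_width", "sd"),
                 dbp_ci = get("dbp_width", "mean"),
                 dbp_ci_sd = get("dbp_width", "sd"),
                 sbp_lower = get("sbp_lower", "mean"),
                 sbp_lower_sd = get("sbp_lower", "sd"),
                 sbp_upper = get("sbp_upper", "mean"),
                 sbp_upper_sd = get("sbp_upper", "sd"),
                 dbp_lower = get("dbp_lower", "mean"),
                 dbp_lower_sd = get("dbp_lower", "sd"),
                 dbp_upper = get("dbp_upper", "mean"),
                 dbp_upper_sd = get("dbp_upper", "sd"),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(accuracy = acc, bhs = bhs, cl = cl),
            class = "bp_comparison_report")
}

#' @export
print.bp_comparison_report <- function(x, ...) {
  cat("Accuracy (ME / SDE, mmHg):\n")
  print(x$accuracy, row.names = FALSE, digits = 3)
  cat("BHS bands and grade:\n")
  print(x$bhs, row.names = FALSE, digits = 3)
  if (!is.null(x$cl)) {
    cat("Confidence limits (mean width and mean limits, across-subject sd):\n")
    print(x$cl, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
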