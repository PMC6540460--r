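# One-sample Kolmogorov-Smirnov machinery: exact finite-sample distribution
# of the two-sided statistic D_n (Marsaglia-Tsang-Wang matrix evaluation),
# exact critical values by numerical inversion, and the test itself.

# P(D_n < d), exact, via the m x m transition-matrix representation with
# floating-point rescaling.  Accurate over the whole support for n up to
# a few thousand; cost grows with ceiling(n * d).
ks_cdf_exact <- function(d, n) {
  if (d <= 0) return(0)
  if (d >= 1) return(1)
  nd <- n * d
  k <- ceiling(nd)
  h <- k - nd
  m <- 2L * k - 1L
  ij <- outer(seq_len(m), seq_len(m), function(i, j) i - j + 1L)
  H <- matrix(as.numeric(ij >= 0L), m, m)
  H[, 1] <- H[, 1] - h^seq_len(m)
  H[m, ] <- H[m, ] - h^(m - seq_len(m) + 1L)
  H[m, 1] <- H[m, 1] + if (2 * h - 1 > 0) (2 * h - 1)^m else 0
  pos <- ij > 0L
  H[pos] <- H[pos] / factorial(ij[pos])
  ## H^n by binary exponentiation with base-1e140 rescaling
  scale_mat <- function(A, eA) {
    v <- A[k, k]
    if (is.finite(v) && v > 1e140) {
      A <- A / 1e140
      eA <- eA + 140L
    }
    list(A = A, e = eA)
  }
  P <- diag(m); eP <- 0L
  base <- H; eB <- 0L
  pow <- n
  while (pow > 0) {
    if (pow %% 2 == 1) {
      P <- P %*% base
      eP <- eP + eB
      s <- scale_mat(P, eP); P <- s$A; eP <- s$e
    }
    pow <- pow %/% 2
    if (pow > 0) {
      base <- base %*% base
      eB <- 2L * eB
      s <- scale_mat(base, eB); base <- s$A; eB <- s$e
    }
  }
  s <- P[k, k]
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) {
      s <- s * 1e140
      eP <- eP - 140L
    }
  }
  out <- s * 10^eP   # eP tracks decimal exponent shed during rescaling
  min(max(out, 0), 1)
}

# Asymptotic Kolmogorov CDF K(x) = P(sqrt(n) D_n <= x) as n -> infinity.
kolmogorov_cdf <- function(x) {
  if (x <= 0) return(0)
  kk <- 1:100
  max(0, min(1, 1 - 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * x^2))))
}

#' Exact tail probability of the one-sample KS statistic
#'
#' `P(D_n >= d)` for the two-sided one-sample Kolmogorov-Smirnov statistic
#' under a fully specified continuous null.  Exact (matrix evaluation) for
#' `n <= 10000`, asymptotic Kolmogorov distribution beyond.
#'
#' @param d observed sup-distance.
#' @param n sample size.
#' @param exact force or disable the exact evaluation.
#' @return the p-value.
#' @export
ks_pvalue <- function(d, n, exact = n <= 10000) {
  if (!is_number(d) || d < 0) stop_validation("d must be a non-negative number")
  if (!is_count(n, 1L)) stop_validation("n must be a positive integer")
  if (exact) 1 - ks_cdf_exact(d, n) else 1 - kolmogorov_cdf(sqrt(n) * d)
}

#' Finite-sample KS critical value
#'
#' The two-sided critical value `cv` such that `P(D_n > cv) = alpha` under a
#' fully specified null, found by numerical inversion of the exact
#' finite-sample distribution (asymptotic inversion for `n > 10000`).
#'
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @param exact force or disable the exact evaluation.
#' @return the critical value.
#' @examples
#' ks_cv(100)   # 0.134 at alpha = 0.05
#' @export
ks_cv <- function(n, alpha = 0.05, exact = n <= 10000) {
  if (!is_count(n, 1L)) stop_validation("n must be a positive integer")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be in (0, 1)")
  }
  if (!exact) {
    f <- function(x) 1 - kolmogorov_cdf(x) - alpha
    return(uniroot(f, c(0.2, 3), tol = 1e-10)$root / sqrt(n))
  }
  f <- function(d) (1 - ks_cdf_exact(d, n)) - alpha
  ## bracket around the asymptotic location so the matrix size (which grows
  ## with n * d) stays small; widen only if the root escapes the bracket
  lo <- max(1 / (2 * n), 0.2 / sqrt(n))
  hi <- min(1 - 1e-9, 6 / sqrt(n))
  while (f(lo) < 0 && lo > 1 / (2 * n)) lo <- max(1 / (2 * n), lo / 2)
  while (f(hi) > 0 && hi < 1 - 1e-9) hi <- min(1 - 1e-9, hi * 1.5)
  uniroot(f, lower = lo, upper = hi, tol = 1e-9)$root
}

# Lilliefors-corrected critical value (normal null with estimated
# parameters), Dallal-Wilkinson style approximation for n > 4.
lilliefors_cv <- function(n, alpha = 0.05) {
  coef <- switch(as.character(alpha),
                 "0.1" = 0.819, "0.05" = 0.895, "0.01" = 1.035,
                 stop_validation(
                   "lilliefors critical values available for alpha in {0.01, 0.05, 0.1}"))
  coef / (sqrt(n) - 0.01 + 0.85 / sqrt(n))
}

#' One-sample Kolmogorov-Smirnov normality test
#'
#' Computes the two-sided sup-distance `D` between the empirical CDF of `x`
#' and a normal reference, with both one-sided corrections at the jump
#' points.  By default the reference normal has its mean and standard
#' deviation estimated from `x` itself, but the decision uses the *standard*
#' fully-specified-null critical values and p-values — the convention used
#' when screening bootstrap replicate distributions, which is conservative
#' (estimated parameters shrink `D`).  Set `lilliefors = TRUE` for the
#' corrected critical value (and, when the `nortest` package is available, a
#' corrected p-value).
#'
#' @param x numeric sample, length >= 5.
#' @param alpha significance level.
#' @param mu,sd optional fully specified reference parameters; when omitted
#'   they are estimated from `x`.
#' @param lilliefors use the estimated-parameter (Lilliefors) critical value.
#' @return object of class `ks_result` with fields `h` (1 = reject
#'   normality), `p`, `ks` (the statistic), `cv`, `n`, `alpha`, `mu`, `sd`.
#' @examples
#' ks_test(rnorm(100))
#' @export
ks_test <- function(x, alpha = 0.05, mu = NULL, sd = NULL, lilliefors = FALSE) {
  if (!is.numeric(x) || length(x) < 5L) {
    stop_validation("ks_test needs at least 5 numeric values")
  }
  if (any(!is.finite(x))) stop_validation("x contains non-finite values")
  fitted <- is.null(mu) || is.null(sd)
  if (fitted) {
    mu <- mean(x)
    sd <- stats::sd(x)
    if (sd == 0) stop_validation("degenerate sample: sd is 0")
  }
  n <- length(x)
  fr <- pnorm(sort(x), mu, sd)
  D <- max(seq_len(n) / n - fr, fr - (seq_len(n) - 1L) / n)
  if (lilliefors) {
    cv <- lilliefors_cv(n, alpha)
    p <- if (requireNamespace("nortest", quietly = TRUE) && fitted) {
      nortest::lillie.test(x)$p.value
    } else NA_real_
  } else {
    cv <- ks_cv(n, alpha)
    p <- ks_pvalue(D, n)
  }
  structure(
    list(h = as.integer(D > cv), p = p, ks = D, cv = cv, n = n,
         alpha = alpha, mu = mu, sd = sd, fitted = fitted,
         lilliefors = lilliefors),
    class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "One-sample KS normality test%s (n = %d, alpha = %s)\n",
    if (x$lilliefors) " [Lilliefors]" else "", x$n, format(x$alpha)))
  cat(sprintf("  D = %s, cv = %s, p = %s -> %s\n",
              fmt_num(x$ks), fmt_num(x$cv), fmt_num(x$p),
              if (x$h == 1L) "reject normality" else "normality not rejected"))
  invisible(x)
}
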