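test_that("kurtosis and skewness reproduce hand-computed values", {
  expect_equal(kurtosis(c(-1, 1, -1, 1)), 1)
  expect_equal(kurtosis(c(2, 4, 6, 8)), 1.64)
  expect_equal(skewness(c(0, 0, 1)), sqrt(0.5), tolerance = 1e-12)
  expect_equal(skewness(c(-3, -1, 0, 1, 3)), 0)
  expect_error(kurtosis(rep(2, 10)), class = "oscibp_validation_error")
  expect_error(kurtosis(c(1, 2, 3)), class = "oscibp_validation_error")
})

test_that("central-moment and raw-moment forms agree to 1e-10", {
  ## the raw-moment expansion with sigma^2 = m2 is an algebraic identity
  for (s in 1:20) {
    x <- with_seed_local(s, rnorm(50, 10, 4))
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    raw_kurt <- (mean(x^4) - 4 * mu * mean(x^3) + 6 * mu^2 * m2 + 3 * mu^4) / m2^2
    raw_skew <- (mean(x^3) - 3 * mu * mean(x^2) + 2 * mu^3) / m2^1.5
    expect_equal(kurtosis(x), raw_kurt, tolerance = 1e-10)
    expect_equal(skewness(x), raw_skew, tolerance = 1e-10)
  }
})

test_that("standard-error formulas evaluate exactly and have the right limit", {
  expect_equal(se_kurtosis(1000), 0.15453, tolerance = 1e-4)
  expect_equal(se_skewness(1000), 0.07734, tolerance = 1e-4)
  expect_equal(se_skewness(1e6) / sqrt(6 / 1e6), 1, tolerance = 1e-4)
  expect_error(se_kurtosis(3), class = "oscibp_validation_error")
  expect_error(se_skewness(2), class = "oscibp_validation_error")
})

test_that("moment z-scores use the kurt = 3 / skew = 0 null", {
  x <- with_seed_local(1, rnorm(2000))
  res <- moment_normality_test(x)
  expect_equal(res$kurtosis$z,
               (kurtosis(x) - 3) / se_kurtosis(length(x)), tolerance = 1e-12)
  expect_equal(res$skewness$z,
               skewness(x) / se_skewness(length(x)), tolerance = 1e-12)
  expect_false(res$reject)
})

test_that("joint moment test holds its size and detects heavy tails", {
  rejections <- vapply(1:1500, function(s) {
    moment_normality_test(with_seed_local(s, rnorm(1000)))$reject
  }, logical(1))
  rate <- mean(rejections)
  ## union of two level-alpha tests: between alpha and 2*alpha, plus
  ## binomial simulation noise
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 1500))
  expect_lt(rate, 0.10 + 3 * sqrt(0.10 * 0.90 / 1500))

  power <- mean(vapply(1:200, function(s) {
    moment_normality_test(with_seed_local(s, rt(1000, df = 3)))$reject
  }, logical(1)))
  expect_gt(power, 0.95)
})

test_that("Spearman test recovers exact monotone structure and hand values", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_independence(x, x^3)$r, 1)
  expect_equal(spearman_independence(x, -sqrt(x))$r, -1)
  expect_equal(spearman_independence(x, c(3, 1, 2, 5, 4))$r, 0.6)
  ## invariance under strictly monotone transforms of either argument
  a <- with_seed_local(2, rnorm(40))
  b <- with_seed_local(3, rnorm(40))
  r0 <- spearman_independence(a, b)$r
  expect_equal(spearman_independence(exp(a), b)$r, r0)
  expect_equal(spearman_independence(a, atan(b))$r, r0)
  expect_error(spearman_independence(1:4, 1:5),
               class = "oscibp_validation_error")
})

test_that("Spearman z uses var(r) = 1/(N-1) under independence", {
  res <- spearman_independence(c(2, 4, 1, 5, 3, 6), c(1, 3, 2, 6, 4, 5))
  expect_equal(res$z, res$r * sqrt(5), tolerance = 1e-12)
  ## empirical variance of r across independent pairs approaches 1/(N-1)
  r <- vapply(1:300, function(s) {
    spearman_independence(with_seed_local(s, rnorm(200)),
                          with_seed_local(10000 + s, rnorm(200)))$r
  }, numeric(1))
  expect_equal(var(r), 1 / 199, tolerance = 0.25)
})

test_that("cohort report summarises all statistics and flags degenerates", {
  preds <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:6), each = 5),
    sbp_est = with_seed_local(4, rnorm(30, 112, 3.4)),
    dbp_est = with_seed_local(5, rnorm(30, 66, 3.6)))
  ## one degenerate subject: identical estimates on both arms
  preds[preds$subject_id == "S06", "sbp_est"] <- 120
  preds[preds$subject_id == "S06", "dbp_est"] <- 70
  cls <- cohort_cl(preds, n_rep = 300, seed = 9)
  expect_message(rep <- cohort_normality_report(cls), "excluded 1")
  expect_equal(rep$n_excluded, 1L)
  expect_equal(rep$n_subjects, 5L)
  expect_equal(rep$summary$arm, c("SBP", "DBP"))
  expect_true(all(c("h", "p", "ks", "cv", "kurtosis", "skewness", "corr",
                    "kurtosis_sd") %in% colnames(rep$summary)))
  expect_equal(rep$spearman_var_theoretical, 1 / 299)
  ## both arms of a healthy Gaussian cohort pass the KS screen
  expect_equal(rep$summary$h, c(0, 0))
})
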