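test_that("gaussian_fit reproduces hand-computed and constructed moments", {
  f <- gaussian_fit(c(1, 2, 3, 4, 5))
  expect_equal(f$mean, 3)
  expect_equal(f$sd, sqrt(2.5))
  expect_equal(gaussian_fit(rep(1, 5))$sd, 0)
  ## round-trip of the published exemplary subject fit (mean 95.4, sd 3.36)
  x <- sample_with_stats(95.4, 3.36, 5, seed = 4)
  f2 <- gaussian_fit(x)
  expect_equal(f2$mean, 95.4, tolerance = 1e-12)
  expect_equal(f2$sd, 3.36, tolerance = 1e-12)
  expect_error(gaussian_fit(1), class = "oscibp_validation_error")
})

test_that("artificial samples have the closed-form spread and are reproducible", {
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  a0 <- artificial_sample(oscibp:::as_gaussian_fit(7, 0, 5), 5, 50, seed = 1)
  expect_true(all(a0$values == 7))

  a1 <- artificial_sample(fit, 5, 1e5, seed = 2)
  expect_equal(sd(a1$values), 3.36 / sqrt(5), tolerance = 0.02)
  expect_identical(artificial_sample(fit, 5, 100, seed = 3)$values,
                   artificial_sample(fit, 5, 100, seed = 3)$values)
  expect_false(identical(artificial_sample(fit, 5, 100, seed = 3)$values,
                         artificial_sample(fit, 5, 100, seed = 4)$values))
})

test_that("N = 100 artificial samples pass the KS normality screen", {
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  pass <- vapply(1:200, function(s) {
    ks_test(artificial_sample(fit, 5, 100, seed = s)$values)$h == 0L
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("bias is zero for degenerate fits and CLT-bounded otherwise", {
  a0 <- artificial_sample(oscibp:::as_gaussian_fit(3, 0, 5), 5, 100, seed = 1)
  expect_identical(bootstrap_bias(a0), 0)
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  ok <- vapply(1:300, function(s) {
    abs(bootstrap_bias(artificial_sample(fit, 5, 100, seed = s))) <=
      4 * 3.36 / sqrt(5 * 100)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("bootstrap standard error matches hand values and the moment oracle", {
  art <- artificial_sample(oscibp:::as_gaussian_fit(0, 1, 3), 1, 3, seed = 1)
  art$values <- c(1, 2, 3)
  expect_equal(bootstrap_se(art), 1)
  expect_equal(bootstrap_se(
    artificial_sample(oscibp:::as_gaussian_fit(5, 0, 5), 5, 10, seed = 1)), 0)

  ## two-pass moment oracle to 1e-12 relative
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  a <- artificial_sample(fit, 5, 500, seed = 9)
  v <- a$values
  oracle_se <- sqrt(sum((v - sum(v) / length(v))^2) / (length(v) - 1))
  oracle_bias <- sum(v) / length(v) - 95.4
  expect_equal(bootstrap_se(a), oracle_se, tolerance = 1e-12)
  expect_equal(bootstrap_bias(a), oracle_bias, tolerance = 1e-12)

  a$n_rep <- 1L
  a$values <- a$values[1]
  expect_error(bootstrap_se(a), class = "oscibp_validation_error")
})

test_that("the exemplary subject fit reproduces its bootstrap standard error", {
  ## fit mean 95.4, sd 3.36, inner n = 5, N = 100: Se* concentrates on
  ## 3.36/sqrt(5) = 1.503 (Monte-Carlo sd about 0.11)
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  se <- vapply(1:50, function(s) {
    bootstrap_se(artificial_sample(fit, 5, 100, seed = s))
  }, numeric(1))
  expect_equal(mean(se), 3.36 / sqrt(5), tolerance = 0.03)
  expect_true(all(abs(se - 3.36 / sqrt(5)) < 0.45))
})

test_that("percentile limits of artificial samples contain the source mean", {
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  contained <- vapply(1:300, function(s) {
    d <- bootstrap_diagnostics(artificial_sample(fit, 5, 100, seed = s))
    d$cl_lower <= 95.4 && 95.4 <= d$cl_upper
  }, logical(1))
  expect_gte(mean(contained), 0.95)
})

test_that("bootstrap distributions converge at the 1/sqrt(N) rate", {
  fit <- oscibp:::as_gaussian_fit(95.4, 3.36, 5)
  expect_equal(convergence_check(oscibp:::as_gaussian_fit(1, 0, 5),
                                 5, c(100, 1000), seed = 1)$ks_distance,
               c(0, 0))

  grid <- c(100L, 1000L, 10000L, 100000L)
  dists <- vapply(1:25, function(s) {
    convergence_check(fit, 5, grid, seed = s)$ks_distance
  }, numeric(length(grid)))
  ## monotone improvement from N = 100 to N = 10000 in nearly every seed
  expect_gte(mean(dists[3, ] < dists[1, ]), 0.95)
  ## DKW rate: log-log slope of the mean distance close to -1/2
  slope <- unname(coef(lm(log(rowMeans(dists)) ~ log(grid)))[2])
  expect_equal(slope, -0.5, tolerance = 0.2)
})

test_that("parametric artificial samples agree with a nonparametric oracle", {
  ## for a near-Gaussian source the resampling-with-replacement bootstrap of
  ## the mean is an independent check of the Se* scale
  x <- sample_with_stats(95.4, 3.36, 5, seed = 6)
  fit <- gaussian_fit(x)
  se_par <- bootstrap_se(artificial_sample(fit, 5, 5000, seed = 1))
  se_np <- with_seed_local(2, {
    sd(replicate(5000, mean(sample(x, 5, replace = TRUE))))
  })
  ## nonparametric uses the n-denominator spread: sd * sqrt((n-1)/n)
  expect_equal(se_np, se_par * sqrt(4 / 5), tolerance = 0.05)
})

test_that("cohort augmentation preserves per-subject location and is order-free", {
  coh <- small_cohort(n_subjects = 4, seed = 10)
  art <- augment_cohort(coh, n_art = 200, seed = 5)
  expect_equal(nrow(art), 4 * 200)
  for (id in unique(coh$subject_id)) {
    orig <- coh[coh$subject_id == id, ]
    gen <- art[art$subject_id == id, ]
    expect_equal(mean(gen$ref_sbp), mean(orig$ref_sbp),
                 tolerance = 4 * sd(orig$ref_sbp) / sqrt(200) / mean(orig$ref_sbp))
  }
  ## per-(subject, column) seed derivation: a subject's artificial values do
  ## not depend on which other subjects are present
  art_sub <- augment_cohort(coh[coh$subject_id == "S002", ], n_art = 200,
                            seed = 5)
  expect_equal(art_sub$ref_sbp,
               art[art$subject_id == "S002", "ref_sbp"])
})

test_that("augmentation diagnostics mirror the per-feature layout", {
  coh <- small_cohort(n_subjects = 3, seed = 12)
  d <- augmentation_diagnostics(coh, n_art = 100, seed = 2)
  expect_equal(nrow(d), 3 * (11 + 2))
  expect_true(all(c("theta_hat", "theta_star", "cl_lower", "cl_upper",
                    "bias", "se_hat", "se_star") %in% colnames(d)))
  expect_true(all(d$cl_lower <= d$cl_upper))
  ## artificial spread is the sd of a 5-draw mean: about se_hat / sqrt(5)
  expect_equal(median(d$se_star / (d$se_hat / sqrt(5))), 1, tolerance = 0.2)
})
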