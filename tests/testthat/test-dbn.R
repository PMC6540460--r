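test_that("standardizer round-trips and names offending columns", {
  X <- matrix(with_seed_local(1, rnorm(60, 5, 2)), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- fit_standardizer(X)
  Z <- apply_standardizer(st, X)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1, 1), tolerance = 1e-10)
  expect_equal(invert_standardizer(st, Z), X, tolerance = 1e-10)
  X[, 2] <- 7
  expect_error(fit_standardizer(X), "b")
})

test_that("zero-parameter RBM gives hidden probability one half", {
  layer <- rbm_layer(3, 4, "bernoulli", seed = 1)
  layer$W[] <- 0
  layer$b_hidden[] <- 0
  v <- matrix(with_seed_local(2, rbinom(12, 1, 0.5)), 4, 3)
  expect_true(all(oscibp:::rbm_hidden_probs(layer, v) == 0.5))
  expect_error(cd_update(layer, matrix(0, 2, 5)),
               class = "oscibp_validation_error")
})

test_that("CD direction agrees with the exact enumerable-RBM gradient", {
  cosims <- vapply(1:40, function(m) {
    layer <- rbm_layer(2, 2, "bernoulli", c(-1, 1), seed = m)
    batch <- matrix(with_seed_local(m, rbinom(16, 1, 0.5)), 8, 2)
    big <- batch[rep(1:8, 500), ]
    g_cd <- with_seed_local(m + 5000, {
      cd_update(layer, big, momentum = 0, cd_steps = 40)$gradient
    })
    cosine(flatten_grad(g_cd), flatten_grad(exact_rbm_gradient(layer, batch)))
  }, numeric(1))
  expect_gt(mean(cosims), 0.99)
})

test_that("reconstruction error falls over pre-training epochs", {
  coh <- small_cohort(n_subjects = 12, seed = 21)
  X <- scale(as.matrix(coh[, bp_feature_names()]))
  drops <- vapply(1:5, function(s) {
    cfg <- train_config(hidden_sizes = 8L, epochs_pretrain = 50L,
                        epochs_finetune = 0L, ensemble_size = 1L, seed = s)
    m <- pretrain_dbn(X, cfg)
    log <- m$pretrain_log
    log$recon_error[log$epoch == 50] < log$recon_error[log$epoch == 1]
  }, logical(1))
  expect_true(all(drops))
})

test_that("pre-training is deterministic and respects the layer plan", {
  coh <- small_cohort(n_subjects = 6, seed = 22)
  X <- scale(as.matrix(coh[, bp_feature_names()]))
  cfg <- train_config(epochs_pretrain = 1L, epochs_finetune = 0L, seed = 5)
  m <- pretrain_dbn(X, cfg)
  widths <- c(nrow(m$layers[[1]]$W), vapply(m$layers, function(l) ncol(l$W), 0L))
  expect_equal(widths, c(11L, 32L, 32L, 32L))
  expect_equal(m$layers[[1]]$visible_kind, "gaussian")
  expect_true(all(vapply(m$layers[-1], `[[`, "", "visible_kind") == "bernoulli"))
  m2 <- pretrain_dbn(X, cfg)
  expect_identical(m$layers, m2$layers)
  ## zero epochs: weights equal the random initialization
  cfg0 <- train_config(epochs_pretrain = 0L, seed = 5)
  m0 <- pretrain_dbn(X, cfg0)
  init <- rbm_layer(11, 32, "gaussian", cfg0$init_range,
                    seed = oscibp:::derive_seed(5, 7L, 1L))
  expect_identical(m0$layers[[1]]$W, init$W)
})

test_that("back-propagated gradients match central finite differences", {
  net <- list(
    W = list(matrix(with_seed_local(1, rnorm(6, 0, 0.5)), 2, 3),
             matrix(with_seed_local(2, rnorm(6, 0, 0.5)), 3, 2)),
    b = list(with_seed_local(3, rnorm(3, 0, 0.2)),
             with_seed_local(4, rnorm(2, 0, 0.2))))
  X <- matrix(with_seed_local(5, rnorm(10)), 5, 2)
  Y <- matrix(with_seed_local(6, rnorm(10)), 5, 2)
  g <- oscibp:::net_gradients(net, X, Y)
  h <- 1e-5
  for (l in 1:2) {
    for (i in seq_along(net$W[[l]])) {
      np <- net; np$W[[l]][i] <- np$W[[l]][i] + h
      nm <- net; nm$W[[l]][i] <- nm$W[[l]][i] - h
      fd <- (oscibp:::net_gradients(np, X, Y)$loss -
               oscibp:::net_gradients(nm, X, Y)$loss) / (2 * h)
      expect_equal(g$W[[l]][i], fd, tolerance = 1e-5)
    }
    for (i in seq_along(net$b[[l]])) {
      np <- net; np$b[[l]][i] <- np$b[[l]][i] + h
      nm <- net; nm$b[[l]][i] <- nm$b[[l]][i] - h
      fd <- (oscibp:::net_gradients(np, X, Y)$loss -
               oscibp:::net_gradients(nm, X, Y)$loss) / (2 * h)
      expect_equal(g$b[[l]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("fine-tuning with zero learning rate leaves the model fixed", {
  coh <- small_cohort(n_subjects = 6, seed = 23)
  X <- scale(as.matrix(coh[, bp_feature_names()]))
  Y <- scale(as.matrix(coh[, c("ref_sbp", "ref_dbp")]))
  cfg <- train_config(hidden_sizes = 8L, epochs_pretrain = 2L,
                      epochs_finetune = 10L, lr_finetune = 0, seed = 6)
  m <- pretrain_dbn(X, cfg)
  m1 <- fine_tune_dbn(m, X, Y, cfg)
  net0 <- oscibp:::dbn_to_net(m, oscibp:::derive_seed(6, 13L))
  expect_identical(m1$net$W, net0$W)
  expect_equal(unique(round(m1$finetune_log$loss, 12)),
               m1$finetune_log$loss[1])
})

test_that("fine-tuning reduces the training loss", {
  coh <- small_cohort(n_subjects = 10, seed = 24)
  X <- scale(as.matrix(coh[, bp_feature_names()]))
  Y <- scale(as.matrix(coh[, c("ref_sbp", "ref_dbp")]))
  drops <- vapply(1:5, function(s) {
    cfg <- train_config(hidden_sizes = c(8L, 8L), epochs_pretrain = 5L,
                        epochs_finetune = 40L, seed = s)
    m <- fine_tune_dbn(pretrain_dbn(X, cfg), X, Y, cfg)
    tail(m$finetune_log$loss, 1) < m$finetune_log$loss[1]
  }, logical(1))
  expect_true(all(drops))
})

test_that("forward pass matches hand computation and the mean-output case", {
  ## 1-visible, 1-hidden toy: y = w2 * sigm(w1 x + c) + b
  net <- list(W = list(matrix(1, 1, 1), matrix(2, 1, 1)), b = list(0, 1))
  out <- oscibp:::net_forward(net, matrix(0, 1, 1))
  expect_equal(out[[3]][1, 1], 2 * 0.5 + 1)

  ## all-zero read-out predicts the stored target means for any input
  model <- structure(list(
    layers = list(structure(list(W = matrix(0, 2, 3), b_hidden = rep(0, 3),
                                 c_visible = rep(0, 2),
                                 visible_kind = "gaussian"),
                            class = "rbm_layer")),
    net = list(W = list(matrix(0, 2, 3), matrix(0, 3, 2)),
               b = list(rep(0, 3), c(0, 0))),
    feature_stats = structure(list(mean = c(0, 0), sd = c(1, 1)),
                              class = "bp_standardizer"),
    target_stats = structure(list(mean = c(112, 66.5), sd = c(13, 9)),
                             class = "bp_standardizer"),
    config = train_config()), class = "bp_dbn")
  p <- predict(model, matrix(with_seed_local(7, rnorm(10)), 5, 2))
  expect_true(all(p[, "sbp"] == 112))
  expect_true(all(p[, "dbp"] == 66.5))
  expect_error(predict(model, matrix(0, 2, 5)),
               class = "oscibp_validation_error")
})

test_that("predictions are equivariant to matched feature/mean shifts", {
  coh <- small_cohort(n_subjects = 8, seed = 25)
  X <- as.matrix(coh[, bp_feature_names()])
  Y <- as.matrix(coh[, c("ref_sbp", "ref_dbp")])
  cfg <- fast_train_config(seed = 8)
  m <- train_dbn(X, Y, cfg)
  p0 <- predict(m, X)
  X2 <- X
  X2[, 3] <- X2[, 3] + 11
  m2 <- m
  m2$feature_stats$mean[3] <- m2$feature_stats$mean[3] + 11
  expect_equal(predict(m2, X2), p0, tolerance = 1e-12)
})

test_that("a one-member ensemble equals its member and averaging reduces spread", {
  coh <- small_cohort(n_subjects = 8, seed = 26)
  halves <- split_cohort(coh, 6)
  cfg <- fast_train_config(ensemble_size = 1L, seed = 9)
  pred <- ensemble_train_predict(halves$train, halves$test, cfg,
                                 n_art = 15, keep_models = TRUE)
  model <- attr(pred, "models")[[1]]
  direct <- predict(model,
                    as.matrix(halves$test[, bp_feature_names()]))
  expect_equal(pred$sbp_est, unname(direct[, "sbp"]), tolerance = 1e-12)

  cfg3 <- fast_train_config(ensemble_size = 3L, seed = 9)
  pred3 <- ensemble_train_predict(halves$train, halves$test, cfg3, n_art = 15)
  mem <- attr(pred3, "member_estimates")
  ens_sde <- sd(pred3$sbp_est - halves$test$ref_sbp)
  mem_sde <- apply(mem[, 1, ], 2, function(e) sd(e - halves$test$ref_sbp))
  expect_lte(ens_sde, max(mem_sde) + 1e-9)
})

test_that("ensemble meets the AAMI bounds on a synthetic cohort", {
  ## reduced problem size: 30 subjects, 3 members, short training — the
  ## feature noise floor leaves ~3 mmHg attainable error
  coh <- small_cohort(n_subjects = 30, seed = 8)
  halves <- split_cohort(coh, 20)
  cfg <- train_config(hidden_sizes = c(16L, 16L), epochs_pretrain = 60L,
                      epochs_finetune = 120L, ensemble_size = 3L, seed = 2)
  pred <- ensemble_train_predict(halves$train, halves$test, cfg, n_art = 30)
  s <- error_summary(pred$sbp_est, pred$ref_sbp)
  d <- error_summary(pred$dbp_est, pred$ref_dbp)
  expect_lt(abs(s$me), 5)
  expect_lt(s$sde, 8)
  expect_lt(abs(d$me), 5)
  expect_lt(d$sde, 8)
  expect_true(aami_pass(s) && aami_pass(d))
})

test_that("a noiseless linear target map is recovered to under 1 mmHg", {
  coh <- generate_cohort(cohort_config(n_subjects = 60, feature_noise_sd = 0.3,
                                       seed = 5))
  X <- as.matrix(coh[, bp_feature_names()])
  A <- cbind(c(4, 2, 1, 0.5, 1, 0.5, 0.3, 1, 2, 0.4, 0.2),
             c(1, 3, 0.5, 2, 0.8, 0.2, 1, 0.5, 0.3, 2, 0.1))
  Y <- X %*% A
  Y <- sweep(Y, 2, c(112, 66.5) - colMeans(Y), "+")
  tr <- 1:250
  te <- 251:300
  cfg <- train_config(hidden_sizes = c(16L, 16L), ensemble_size = 2L, seed = 3)
  models <- lapply(1:2, function(m) {
    c2 <- cfg
    c2$seed <- oscibp:::derive_seed(3, 29L, m)
    train_dbn(X[tr, ], Y[tr, ], c2)
  })
  p <- Reduce(`+`, lapply(models, predict, newdata = X[te, ])) / 2
  expect_lt(sqrt(mean((p[, 1] - Y[te, 1])^2)), 1)
  expect_lt(sqrt(mean((p[, 2] - Y[te, 2])^2)), 1)
})

test_that("models round-trip through the portable JSON format", {
  coh <- small_cohort(n_subjects = 6, seed = 27)
  X <- as.matrix(coh[, bp_feature_names()])
  Y <- as.matrix(coh[, c("ref_sbp", "ref_dbp")])
  m <- train_dbn(X, Y, fast_train_config(seed = 10))
  path <- withr::local_tempfile(fileext = ".json")
  save_dbn(m, path)
  m2 <- load_dbn(path)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-10)
  ens <- dbn_ensemble(list(m, m))
  path2 <- withr::local_tempfile(fileext = ".json")
  save_dbn(ens, path2)
  expect_equal(predict(load_dbn(path2), X), predict(m, X), tolerance = 1e-10)
})
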