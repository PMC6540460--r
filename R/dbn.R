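# Deep-belief-network regression: a Gaussian-Bernoulli RBM first layer and
# stacked Bernoulli-Bernoulli RBMs, pre-trained greedily by contrastive
# divergence, then unrolled into a sigmoid feed-forward net with a linear
# two-output read-out and fine-tuned by momentum back-propagation.

#' Training configuration for the DBN regressor
#'
#' Defaults follow the published training recipe: three hidden layers of 32
#' units, weight learning rate 0.001 and bias learning rates 0.01 in
#' pre-training, momentum 0.9, 200 pre-training and 200 fine-tuning epochs,
#' initial weights and biases uniform on (-1, 1), sigmoid hidden
#' activations, ensemble of 50 independently seeded members.  The
#' fine-tuning learning rate, batch size and CD steps are not part of the
#' published recipe; package defaults are 0.03, 10 and 1.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param lr_weights,lr_vbias,lr_hbias contrastive-divergence learning rates
#'   for weights, visible biases and hidden biases.
#' @param lr_finetune back-propagation learning rate.
#' @param momentum momentum coefficient in `[0, 1)` (both phases).
#' @param epochs_pretrain,epochs_finetune training epochs (0 allowed:
#'   pre-training 0 leaves the random initialization untouched).
#' @param batch_size mini-batch size.
#' @param cd_steps Gibbs steps per CD update.
#' @param init_range range of the uniform weight/bias initialization.
#' @param ensemble_size number of ensemble members.
#' @param bagging resample the training rows (with replacement) per member
#'   instead of only reseeding.
#' @param seed root seed for all training randomness.
#' @return object of class `bp_train_config`.
#' @export
train_config <- function(hidden_sizes = c(32L, 32L, 32L),
                         lr_weights = 0.001, lr_vbias = 0.01, lr_hbias = 0.01,
                         lr_finetune = 0.03, momentum = 0.9,
                         epochs_pretrain = 200L, epochs_finetune = 200L,
                         batch_size = 10L, cd_steps = 1L,
                         init_range = c(-1, 1), ensemble_size = 50L,
                         bagging = FALSE, seed = 1L) {
  cfg <- list(hidden_sizes = as.integer(hidden_sizes),
              lr_weights = lr_weights, lr_vbias = lr_vbias,
              lr_hbias = lr_hbias, lr_finetune = lr_finetune,
              momentum = momentum,
              epochs_pretrain = as.integer(epochs_pretrain),
              epochs_finetune = as.integer(epochs_finetune),
              batch_size = as.integer(batch_size),
              cd_steps = as.integer(cd_steps),
              init_range = as.numeric(init_range),
              ensemble_size = as.integer(ensemble_size),
              bagging = isTRUE(bagging), seed = seed)
  class(cfg) <- "bp_train_config"
  validate_train_config(cfg)
  cfg
}

validate_train_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop_validation(sprintf("invalid train config: `%s` %s", field, why))
  }
  chk(length(cfg$hidden_sizes) >= 1L && all(cfg$hidden_sizes >= 1L),
      "hidden_sizes", "must be positive integers")
  for (f in c("lr_weights", "lr_vbias", "lr_hbias", "lr_finetune")) {
    chk(is_number(cfg[[f]]) && cfg[[f]] >= 0, f, "must be >= 0")
  }
  chk(is_number(cfg$momentum) && cfg$momentum >= 0 && cfg$momentum < 1,
      "momentum", "must be in [0, 1)")
  chk(cfg$epochs_pretrain >= 0L, "epochs_pretrain", "must be >= 0")
  chk(cfg$epochs_finetune >= 0L, "epochs_finetune", "must be >= 0")
  chk(cfg$batch_size >= 1L, "batch_size", "must be >= 1")
  chk(cfg$cd_steps >= 1L, "cd_steps", "must be >= 1")
  chk(length(cfg$init_range) == 2L && cfg$init_range[1] < cfg$init_range[2],
      "init_range", "must be an increasing pair")
  chk(cfg$ensemble_size >= 1L, "ensemble_size", "must be >= 1")
  invisible(cfg)
}

## ---- standardization ------------------------------------------------------

#' Fit a per-column standardizer
#'
#' Column means and n-1 standard deviations; the Gaussian-Bernoulli input
#' layer assumes roughly unit-variance visibles, and the linear read-out is
#' trained on standardized targets.
#'
#' @param X numeric matrix or data.frame of columns to standardize.
#' @return object of class `bp_standardizer` (fields `mean`, `sd`).
#' @export
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    stop_validation(paste0("constant column(s) cannot be standardized: ",
                           paste(colnames(X)[zero] %||% which(zero),
                                 collapse = ", ")))
  }
  structure(list(mean = mu, sd = sdv), class = "bp_standardizer")
}

#' @rdname fit_standardizer
#' @param st a fitted `bp_standardizer`.
#' @export
apply_standardizer <- function(st, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(st, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, st$sd, "*"), 2, st$mean, "+")
}

## ---- RBM layers and contrastive divergence --------------------------------

#' Initialize one RBM layer
#'
#' @param n_visible,n_hidden layer widths.
#' @param visible_kind `"gaussian"` (first layer, real-valued standardized
#'   visibles with unit variance) or `"bernoulli"`.
#' @param init_range uniform initialization range for weights and biases.
#' @param seed integer seed.
#' @return object of class `rbm_layer`: `W` (visible x hidden), `b_hidden`,
#'   `c_visible`, `visible_kind`.
#' @export
rbm_layer <- function(n_visible, n_hidden,
                      visible_kind = c("bernoulli", "gaussian"),
                      init_range = c(-1, 1), seed = 1L) {
  visible_kind <- match.arg(visible_kind)
  with_seed(seed, {
    structure(
      list(
        W = matrix(runif(n_visible * n_hidden, init_range[1], init_range[2]),
                   n_visible, n_hidden),
        b_hidden = runif(n_hidden, init_range[1], init_range[2]),
        c_visible = runif(n_visible, init_range[1], init_range[2]),
        visible_kind = visible_kind),
      class = "rbm_layer")
  })
}

rbm_hidden_probs <- function(layer, v) {
  sigm(sweep(v %*% layer$W, 2, layer$b_hidden, "+"))
}

rbm_visible_mean <- function(layer, h) {
  act <- sweep(h %*% t(layer$W), 2, layer$c_visible, "+")
  if (layer$visible_kind == "bernoulli") sigm(act) else act
}

sample_bernoulli <- function(p) {
  (matrix(runif(length(p)), nrow(p), ncol(p)) < p) * 1
}

zero_velocity <- function(layer) {
  list(W = layer$W * 0, c_visible = layer$c_visible * 0,
       b_hidden = layer$b_hidden * 0)
}

#' One contrastive-divergence update
#'
#' Positive phase: hidden probabilities given the data batch.  Negative
#' phase: `cd_steps` alternating Gibbs steps with sampled hidden (and, for
#' Bernoulli layers, sampled visible) states; the final statistics pair the
#' last visible state with its hidden probabilities (Rao-Blackwellised, so
#' the estimate is unbiased for the exact gradient as k grows).  The
#' gradient `<v h>_data - <v h>_recon` is applied through a classical
#' momentum velocity.  Uses the current RNG stream; seed at a higher level.
#'
#' @param layer an [rbm_layer()].
#' @param batch matrix (rows = cases, columns = visible units).
#' @param lr_weights,lr_vbias,lr_hbias learning rates.
#' @param momentum momentum coefficient.
#' @param velocity velocity list from the previous call, or `NULL` to start
#'   from zero.
#' @param cd_steps number of Gibbs steps k.
#' @return list with the updated `layer`, `velocity`, the batch
#'   `recon_error` (mean squared first-step reconstruction error) and the
#'   raw `gradient`.
#' @export
cd_update <- function(layer, batch, lr_weights = 0.001, lr_vbias = 0.01,
                      lr_hbias = 0.01, momentum = 0.9, velocity = NULL,
                      cd_steps = 1L) {
  batch <- as.matrix(batch)
  if (ncol(batch) != nrow(layer$W)) {
    stop_validation(sprintf("batch has %d columns but layer expects %d visibles",
                            ncol(batch), nrow(layer$W)))
  }
  if (is.null(velocity)) velocity <- zero_velocity(layer)
  B <- nrow(batch)

  p_h0 <- rbm_hidden_probs(layer, batch)
  h <- sample_bernoulli(p_h0)
  recon_error <- NA_real_
  v <- batch
  p_h <- p_h0
  for (s in seq_len(cd_steps)) {
    v_mean <- rbm_visible_mean(layer, h)
    if (s == 1L) recon_error <- mean((batch - v_mean)^2)
    ## proper Gibbs transition: Bernoulli visibles are sampled (Gaussian
    ## visibles use the mean, the usual stabilisation); pairing the sampled
    ## v with p(h | v) keeps the final statistics Rao-Blackwellised and
    ## unbiased in the k -> infinity limit
    v <- if (layer$visible_kind == "bernoulli") sample_bernoulli(v_mean) else v_mean
    p_h <- rbm_hidden_probs(layer, v)
    if (s < cd_steps) h <- sample_bernoulli(p_h)
  }

  grad <- list(
    W = (crossprod(batch, p_h0) - crossprod(v, p_h)) / B,
    c_visible = colMeans(batch) - colMeans(v),
    b_hidden = colMeans(p_h0) - colMeans(p_h))

  velocity$W <- momentum * velocity$W + lr_weights * grad$W
  velocity$c_visible <- momentum * velocity$c_visible + lr_vbias * grad$c_visible
  velocity$b_hidden <- momentum * velocity$b_hidden + lr_hbias * grad$b_hidden
  layer$W <- layer$W + velocity$W
  layer$c_visible <- layer$c_visible + velocity$c_visible
  layer$b_hidden <- layer$b_hidden + velocity$b_hidden
  if (!all(is.finite(layer$W))) {
    stop_numerical("RBM weights diverged (non-finite); try a smaller learning rate")
  }
  list(layer = layer, velocity = velocity, recon_error = recon_error,
       gradient = grad)
}

train_rbm_layer <- function(layer, X, config) {
  velocity <- zero_velocity(layer)
  n <- nrow(X)
  log <- numeric(config$epochs_pretrain)
  for (epoch in seq_len(config$epochs_pretrain)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    errs <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      step <- cd_update(layer, X[idx, , drop = FALSE],
                        config$lr_weights, config$lr_vbias, config$lr_hbias,
                        config$momentum, velocity, config$cd_steps)
      layer <- step$layer
      velocity <- step$velocity
      errs[bi] <- step$recon_error
    }
    log[epoch] <- mean(errs)
  }
  list(layer = layer, recon_log = log)
}

#' Greedy layer-wise pre-training
#'
#' Trains the Gaussian-Bernoulli first layer on the standardized inputs,
#' then each Bernoulli-Bernoulli layer on the hidden activation
#' probabilities of the layer below.  Deterministic given `config$seed`.
#'
#' @param X standardized input matrix (rows = cases).
#' @param config a [train_config()].
#' @return object of class `bp_dbn` holding the trained `layers` and the
#'   per-(layer, epoch) reconstruction-error log; the read-out is added by
#'   [fine_tune_dbn()].
#' @export
pretrain_dbn <- function(X, config) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_validation("inputs contain non-finite values")
  sizes <- c(ncol(X), config$hidden_sizes)
  layers <- vector("list", length(config$hidden_sizes))
  logs <- list()
  with_seed(derive_seed(config$seed, 7L), {
    input <- X
    for (l in seq_along(layers)) {
      kind <- if (l == 1L) "gaussian" else "bernoulli"
      layer <- rbm_layer(sizes[l], sizes[l + 1L], kind, config$init_range,
                         seed = derive_seed(config$seed, 7L, l))
      if (config$epochs_pretrain > 0L) {
        fit <- train_rbm_layer(layer, input, config)
        layer <- fit$layer
        logs[[l]] <- data.frame(layer = l,
                                epoch = seq_along(fit$recon_log),
                                recon_error = fit$recon_log)
      }
      layers[[l]] <- layer
      input <- rbm_hidden_probs(layer, input)
    }
  })
  structure(
    list(layers = layers, net = NULL,
         feature_stats = NULL, target_stats = NULL,
         config = config,
         pretrain_log = if (length(logs)) do.call(rbind, logs) else NULL,
         finetune_log = NULL),
    class = "bp_dbn")
}

## ---- feed-forward net: forward pass and back-propagation ------------------

# net: list(W = list of matrices, b = list of vectors); sigmoid on all but
# the last (linear) layer.
dbn_to_net <- function(model, seed) {
  Ws <- lapply(model$layers, `[[`, "W")
  bs <- lapply(model$layers, `[[`, "b_hidden")
  last <- ncol(Ws[[length(Ws)]])
  ir <- model$config$init_range
  out <- with_seed(seed, {
    list(W = matrix(runif(last * 2L, ir[1], ir[2]), last, 2L),
         b = runif(2L, ir[1], ir[2]))
  })
  list(W = c(Ws, list(out$W)), b = c(bs, list(out$b)))
}

net_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) sigm(z) else z
  }
  acts
}

# Batch loss (mean over cases of the summed squared output errors) and its
# gradients with respect to every weight and bias.
net_gradients <- function(net, X, Y) {
  L <- length(net$W)
  B <- nrow(X)
  acts <- net_forward(net, X)
  yhat <- acts[[L + 1L]]
  err <- yhat - Y
  loss <- sum(err^2) / B
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- 2 * err / B
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      a <- acts[[l]]
      delta <- (delta %*% t(net$W[[l]])) * a * (1 - a)
    }
  }
  list(loss = loss, W = gW, b = gb)
}

#' Fine-tune the unrolled network by momentum back-propagation
#'
#' Unrolls the pre-trained stack into a deterministic feed-forward net
#' (sigmoid hidden layers, linear two-output read-out initialized uniformly
#' on the configured range), then minimizes the batch mean of the summed
#' squared standardized-target errors with the momentum update
#' `v <- momentum * v - lr * grad; theta <- theta + v`.
#'
#' @param model a `bp_dbn` from [pretrain_dbn()].
#' @param X standardized feature matrix.
#' @param Y standardized target matrix (2 columns: SBP, DBP).
#' @param config a [train_config()]; `NULL` reuses `model$config`.
#' @return the model with a trained `$net` and a per-epoch loss log.
#' @export
fine_tune_dbn <- function(model, X, Y, config = NULL) {
  config <- config %||% model$config
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  dimnames(X) <- NULL
  dimnames(Y) <- NULL
  if (ncol(Y) != 2L) stop_validation("Y must have 2 columns (SBP, DBP)")
  if (nrow(X) != nrow(Y)) stop_validation("X and Y row counts differ")
  net <- model$net %||% dbn_to_net(model, derive_seed(config$seed, 13L))
  L <- length(net$W)
  velW <- lapply(net$W, function(w) w * 0)
  velb <- lapply(net$b, function(b) b * 0)
  n <- nrow(X)
  log <- numeric(config$epochs_finetune)
  lr <- config$lr_finetune
  mom <- config$momentum
  with_seed(derive_seed(config$seed, 17L), {
    for (epoch in seq_len(config$epochs_finetune)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tot <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        g <- net_gradients(net, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
        if (!is.finite(g$loss)) {
          stop_numerical("fine-tuning diverged (non-finite loss); try a smaller learning rate")
        }
        for (l in seq_len(L)) {
          velW[[l]] <- mom * velW[[l]] - lr * g$W[[l]]
          velb[[l]] <- mom * velb[[l]] - lr * g$b[[l]]
          net$W[[l]] <- net$W[[l]] + velW[[l]]
          net$b[[l]] <- net$b[[l]] + velb[[l]]
        }
        tot <- tot + g$loss * length(idx)
      }
      log[epoch] <- tot / n
    }
  })
  model$net <- net
  model$finetune_log <- if (config$epochs_finetune > 0L) {
    data.frame(epoch = seq_along(log), loss = log)
  } else NULL
  model
}

#' Train a DBN regressor end to end
#'
#' Standardizes features and targets, pre-trains the RBM stack on the
#' features and fine-tunes to the standardized `(SBP, DBP)` targets.
#'
#' @param features numeric matrix/data.frame of inputs (typically the
#'   bootstrap-augmented training features).
#' @param targets two-column matrix/data.frame (`ref_sbp`, `ref_dbp`), mmHg.
#' @param config a [train_config()].
#' @return a fitted `bp_dbn` with standardization statistics attached.
#' @export
train_dbn <- function(features, targets, config = train_config()) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (ncol(targets) != 2L) stop_validation("targets must have 2 columns")
  fs <- fit_standardizer(features)
  ts <- fit_standardizer(targets)
  model <- pretrain_dbn(apply_standardizer(fs, features), config)
  model$feature_stats <- fs
  model$target_stats <- ts
  model <- fine_tune_dbn(model, apply_standardizer(fs, features),
                         apply_standardizer(ts, targets), config)
  model
}

#' Predict blood pressures from features
#'
#' Deterministic forward pass through the fine-tuned network; outputs are
#' de-standardized back to mmHg.
#'
#' @param object a fitted `bp_dbn`.
#' @param newdata feature matrix/data.frame with the training width.
#' @param ... unused.
#' @return matrix with columns `sbp`, `dbp` (mmHg), one row per input row.
#' @export
predict.bp_dbn <- function(object, newdata, ...) {
  if (is.null(object$net)) {
    stop_validation("model has no read-out layer; run fine_tune_dbn() first")
  }
  X <- as.matrix(newdata)
  p <- length(object$feature_stats$mean)
  if (ncol(X) != p) {
    stop_validation(sprintf("newdata has %d columns but the model expects %d",
                            ncol(X), p))
  }
  Xz <- apply_standardizer(object$feature_stats, X)
  acts <- net_forward(object$net, Xz)
  out <- invert_standardizer(object$target_stats, acts[[length(acts)]])
  colnames(out) <- c("sbp", "dbp")
  out
}

#' @export
print.bp_dbn <- function(x, ...) {
  widths <- c(nrow(x$layers[[1]]$W), vapply(x$layers, function(l) ncol(l$W), 0L))
  cat(sprintf("DBN regressor: %s -> 2 (%s)\n",
              paste(widths, collapse = "-"),
              if (is.null(x$net)) "pre-trained only" else "fine-tuned"))
  if (!is.null(x$finetune_log)) {
    cat(sprintf("  final fine-tuning loss: %s (standardized MSE)\n",
                fmt_num(x$finetune_log$loss[nrow(x$finetune_log)])))
  }
  invisible(x)
}

#' Train an ensemble and predict a test cohort
#'
#' Bootstrap-augments the training measurements, trains `ensemble_size`
#' independently seeded DBN members on the artificial set (optionally
#' bagging it) and averages the member predictions over the test
#' measurements.
#'
#' @param train_records,test_records subject-disjoint measurement tables
#'   (see [split_cohort()]).
#' @param config a [train_config()].
#' @param n_art artificial measurements per training subject.
#' @param mode,n_inner augmentation mode, see [augment_cohort()].
#' @param keep_models keep the fitted member models in the result.
#' @return a `data.frame` with `subject_id`, `meas_idx`, `sbp_est`,
#'   `dbp_est` (+ reference columns when present in `test_records`);
#'   `attr(, "member_estimates")` is an `n_test x 2 x ensemble_size` array,
#'   `attr(, "models")` the members when kept.
#' @export
ensemble_train_predict <- function(train_records, test_records,
                                   config = train_config(),
                                   n_art = 100L, mode = "draw", n_inner = 5L,
                                   keep_models = FALSE) {
  overlap <- intersect(unique(train_records$subject_id),
                       unique(test_records$subject_id))
  if (length(overlap) > 0L) {
    stop_validation("train and test sets share subjects; split by subject first")
  }
  art <- augment_cohort(train_records, n_art, mode, n_inner,
                        seed = derive_seed(config$seed, 23L))
  fcols <- feature_columns(train_records)
  Xtr <- as.matrix(art[, fcols, drop = FALSE])
  Ytr <- as.matrix(art[, c("ref_sbp", "ref_dbp")])
  Xte <- as.matrix(test_records[, fcols, drop = FALSE])

  members <- vector("list", config$ensemble_size)
  preds <- array(NA_real_, c(nrow(Xte), 2L, config$ensemble_size))
  for (m in seq_len(config$ensemble_size)) {
    cfg_m <- config
    cfg_m$seed <- derive_seed(config$seed, 29L, m)
    Xm <- Xtr; Ym <- Ytr
    if (config$bagging) {
      idx <- with_seed(derive_seed(config$seed, 31L, m),
                       sample.int(nrow(Xtr), replace = TRUE))
      Xm <- Xtr[idx, , drop = FALSE]
      Ym <- Ytr[idx, , drop = FALSE]
    }
    fit <- train_dbn(Xm, Ym, cfg_m)
    preds[, , m] <- predict(fit, Xte)
    if (keep_models) members[[m]] <- fit
  }
  est <- apply(preds, c(1, 2), mean)
  out <- data.frame(subject_id = test_records$subject_id,
                    meas_idx = test_records$meas_idx,
                    sbp_est = est[, 1], dbp_est = est[, 2],
                    stringsAsFactors = FALSE)
  for (cn in c("ref_sbp", "ref_dbp")) {
    if (cn %in% colnames(test_records)) out[[cn]] <- test_records[[cn]]
  }
  attr(out, "member_estimates") <- preds
  if (keep_models) attr(out, "models") <- members
  out
}

#' Bundle fitted DBNs into an ensemble model
#'
#' @param models list of fitted `bp_dbn` objects.
#' @return object of class `bp_dbn_ensemble`; its `predict` method averages
#'   the member predictions.
#' @export
dbn_ensemble <- function(models) {
  if (length(models) == 0L || !all(vapply(models, inherits, TRUE, "bp_dbn"))) {
    stop_validation("models must be a non-empty list of bp_dbn objects")
  }
  structure(list(members = models), class = "bp_dbn_ensemble")
}

#' @export
predict.bp_dbn_ensemble <- function(object, newdata, ...) {
  preds <- lapply(object$members, predict, newdata = newdata)
  out <- Reduce(`+`, preds) / length(preds)
  colnames(out) <- c("sbp", "dbp")
  out
}

#' @export
print.bp_dbn_ensemble <- function(x, ...) {
  cat(sprintf("DBN ensemble of %d members\n", length(x$members)))
  print(x$members[[1]])
  invisible(x)
}

## ---- serialization --------------------------------------------------------

serialize_dbn <- function(model) {
  list(
    visible_kind = vapply(model$layers, `[[`, "", "visible_kind"),
    layers = lapply(model$layers, function(l) {
      list(W = l$W, b_hidden = l$b_hidden, c_visible = l$c_visible)
    }),
    net = if (!is.null(model$net)) list(W = model$net$W, b = model$net$b),
    feature_stats = unclass(model$feature_stats),
    target_stats = unclass(model$target_stats),
    config = unclass(model$config))
}

deserialize_dbn <- function(ser) {
  as_mat <- function(x) {
    if (is.data.frame(x)) as.matrix(x)
    else if (is.list(x)) do.call(rbind, lapply(x, unlist))
    else as.matrix(x)
  }
  layers <- lapply(seq_along(ser$layers), function(l) {
    li <- ser$layers[[l]]
    structure(list(W = as_mat(li$W), b_hidden = unlist(li$b_hidden),
                   c_visible = unlist(li$c_visible),
                   visible_kind = ser$visible_kind[[l]]),
              class = "rbm_layer")
  })
  net <- if (!is.null(ser$net)) {
    list(W = lapply(ser$net$W, as_mat), b = lapply(ser$net$b, unlist))
  }
  cfg <- lapply(ser$config, unlist)
  cfg$hidden_sizes <- as.integer(cfg$hidden_sizes)
  cfg$init_range <- as.numeric(cfg$init_range)
  class(cfg) <- "bp_train_config"
  stats_of <- function(s) {
    structure(list(mean = unlist(s$mean), sd = unlist(s$sd)),
              class = "bp_standardizer")
  }
  structure(
    list(layers = layers, net = net,
         feature_stats = stats_of(ser$feature_stats),
         target_stats = stats_of(ser$target_stats),
         config = cfg, pretrain_log = NULL, finetune_log = NULL),
    class = "bp_dbn")
}

#' Save / load a fitted DBN (or ensemble) as portable JSON
#'
#' The file carries a format version, the layer weights and biases, the
#' read-out, the standardization statistics and the training configuration;
#' ensembles store every member, so reloading reproduces the averaged
#' predictions exactly.
#'
#' @param model a fitted `bp_dbn` or [dbn_ensemble()].
#' @param path file path.
#' @export
save_dbn <- function(model, path) {
  ser <- if (inherits(model, "bp_dbn_ensemble")) {
    list(format = "oscibp-dbn-ensemble", version = 1L,
         members = lapply(model$members, serialize_dbn))
  } else {
    c(list(format = "oscibp-dbn", version = 1L), serialize_dbn(model))
  }
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       simplifyVector = FALSE)
  invisible(path)
}

#' @rdname save_dbn
#' @return `load_dbn()` returns the restored model.
#' @export
load_dbn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  ser$visible_kind <- unlist(ser$visible_kind)
  if (identical(ser$format, "oscibp-dbn-ensemble")) {
    dbn_ensemble(lapply(ser$members, function(m) {
      m$visible_kind <- unlist(m$visible_kind)
      deserialize_dbn(m)
    }))
  } else if (identical(ser$format, "oscibp-dbn")) {
    deserialize_dbn(ser)
  } else {
    stop_validation("not an oscibp DBN model file")
  }
}
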