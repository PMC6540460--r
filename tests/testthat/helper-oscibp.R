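# Shared fixtures: all synthetic, built in code at test time.

small_cohort <- function(n_subjects = 10, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}

fast_train_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_sizes = c(8L, 8L), epochs_pretrain = 15L,
         epochs_finetune = 25L, ensemble_size = 2L),
    list(...))
  do.call(train_config, args)
}

# A sample with exactly the requested mean and (n-1) sd, for fit round-trips.
sample_with_stats <- function(mean, sd, n, seed = 1) {
  z <- with_seed_local(seed, stats::rnorm(n))
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Exact log-likelihood gradient for an enumerable Bernoulli-Bernoulli RBM
# (brute force over all visible x hidden configurations).
exact_rbm_gradient <- function(layer, batch) {
  nv <- nrow(layer$W); nh <- ncol(layer$W)
  V <- as.matrix(expand.grid(rep(list(0:1), nv)))
  H <- as.matrix(expand.grid(rep(list(0:1), nh)))
  states_v <- V[rep(seq_len(nrow(V)), each = nrow(H)), , drop = FALSE]
  states_h <- H[rep(seq_len(nrow(H)), times = nrow(V)), , drop = FALSE]
  en <- rowSums((states_v %*% layer$W) * states_h) +
    states_v %*% layer$c_visible + states_h %*% layer$b_hidden
  p <- exp(en - max(en)); p <- as.numeric(p / sum(p))
  ph <- oscibp:::rbm_hidden_probs(layer, batch)
  list(W = crossprod(batch, ph) / nrow(batch) - t(states_v) %*% (states_h * p),
       c_visible = colMeans(batch) - colSums(states_v * p),
       b_hidden = colMeans(ph) - colSums(states_h * p))
}

flatten_grad <- function(g) c(g$W, g$c_visible, g$b_hidden)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
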