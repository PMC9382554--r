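# Shared fixtures and independent oracles, built in code at test time.

binary_labels <- function() label_set(c("No", "Yes"), null_label = "No")

tiny_corpus <- function(n = 6, seed = 3, noise = 0, lengths = c(5, 9)) {
  generate_corpus(synthetic_spec(
    n_instances = n, label_set = binary_labels(), vocab_size = 60,
    length_range = lengths, trigger_map = list(Yes = "binds"),
    noise_rate = noise, task = "binary", seed = seed))
}

toy_config <- function(...) {
  defaults <- list(embedding_dim = 8, hidden_dim = 8, chunk_size = 4,
                   heads = 2, gcn_layers = 1, dropout = 0, lr = 0.3,
                   epochs = 2, batch_size = 1, seed = 2, task = "binary")
  do.call(relgcn_config, utils::modifyList(defaults, list(...)))
}

toy_model <- function(corpus = tiny_corpus(), config = toy_config(),
                      dim = 8, seed = 5) {
  vocab <- build_vocabulary(corpus, dim = dim, seed = seed)
  relgcn:::model_init(config, vocab, binary_labels())
}

# Independent plain-LSTM reference (forward only), written directly from the
# standard gate equations; shares nothing with the package's recurrence code.
reference_lstm <- function(X, W, U, b) {
  d <- ncol(U) / 4
  n <- nrow(X)
  h <- matrix(0, n, d)
  h_prev <- numeric(d); c_prev <- numeric(d)
  sg <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(n)) {
    z <- drop(X[t, ] %*% W) + drop(h_prev %*% U) + b
    f <- sg(z[1:d]); i <- sg(z[d + 1:d]); o <- sg(z[2 * d + 1:d])
    g <- tanh(z[3 * d + 1:d])
    c_prev <- f * c_prev + i * g
    h_prev <- o * tanh(c_prev)
    h[t, ] <- h_prev
  }
  h
}

# Independent entropy of a probability vector (natural log)
entropy_ref <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Independent precision/recall/F1 from an explicit confusion table,
# computed label-by-label with plain arithmetic.
prf_ref <- function(pred, gold, labels, null_label = NULL) {
  tp <- fp <- fn <- stats::setNames(numeric(length(labels)), labels)
  for (l in labels) {
    tp[l] <- sum(pred == l & gold == l)
    fp[l] <- sum(pred == l & gold != l)
    fn[l] <- sum(pred != l & gold == l)
  }
  pos <- setdiff(labels, null_label)
  TP <- sum(tp[pos]); FP <- sum(fp[pos]); FN <- sum(fn[pos])
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  list(accuracy = mean(pred == gold),
       micro_f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# flatten helpers for gradient checks
flat_grads <- function(model, g) {
  z <- relgcn:::grads_scale(model$params, 0)
  relgcn:::params_flatten(relgcn:::params_axpy(z, g, 1))
}

numeric_grad <- function(f, theta, eps = 1e-5, idx = seq_along(theta)) {
  vapply(idx, function(j) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}
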