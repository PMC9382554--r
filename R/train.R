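#' Fit the syntax-enhanced GCN relation classifier
#'
#' Trains the full model -- ordered-neuron LSTM encoder, multi-head attention
#' adjacency, Gaussian-kernel equalization, GCN propagation, entity-aware
#' feedforward classifier -- by stochastic gradient descent on the
#' cross-entropy, with a multiplicative per-epoch learning-rate decay and
#' early stopping on the development metric. All gradients are analytic
#' (hand-derived backpropagation); runs are reproducible on CPU under a fixed
#' `config$seed`.
#'
#' @param corpus list of [relation_instance] training examples.
#' @param dev optional development corpus; when `NULL`, a seeded 10\% split of
#'   `corpus` is held out.
#' @param config a [relgcn_config].
#' @param labels optional [label_set]; inferred from the data when `NULL`
#'   (sorted unique labels; `"None"`/`"No"` recognized as the null class).
#' @param vocab optional [build_vocabulary] result; built from the training
#'   and dev tokens when `NULL`.
#' @param embeddings_path optional pretrained embedding text file used when
#'   building the vocabulary.
#' @param verbose print one line per epoch.
#' @return an object of class `"relgcn"`: the best-dev parameters, config,
#'   vocabulary, label set, and a per-epoch `log` data frame (epoch, learning
#'   rate, mean training loss, dev accuracy, dev metric).
#' @seealso [predict.relgcn], [evaluate], [crossvalidate]
#' @export
relgcn <- function(corpus, dev = NULL, config = relgcn_config(),
                   labels = NULL, vocab = NULL, embeddings_path = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(config, "relgcn_config"))
  if (!length(corpus)) stop("empty training corpus", call. = FALSE)
  rng <- local_rng(config$seed * 7L + 29L)

  if (is.null(dev)) {
    n_dev <- max(1L, floor(0.1 * length(corpus)))
    idx <- rng$sample(seq_along(corpus), n_dev)
    dev <- corpus[idx]
    corpus <- corpus[-idx]
  }
  if (is.null(labels)) {
    labs <- sort(unique(vapply(c(corpus, dev), `[[`, character(1), "label")))
    nul <- intersect(c("None", "No", "null", "NULL"), labs)
    labels <- label_set(labs, null_label = if (length(nul)) nul[1])
  }
  train_labs <- vapply(corpus, `[[`, character(1), "label")
  dev_labs <- vapply(dev, `[[`, character(1), "label")
  bad <- setdiff(unique(c(train_labs, dev_labs)), labels$labels)
  if (length(bad))
    stop("labels absent from the label set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(vocab))
    vocab <- build_vocabulary(c(corpus, dev), embeddings_path,
                              dim = config$embedding_dim, seed = config$seed)

  model <- model_init(config, vocab, labels)
  velocity <- NULL
  best <- list(metric = -Inf, params = model$params, epoch = 0L)
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), dev_accuracy = numeric(),
                    dev_metric = numeric())
  stall <- 0L
  n <- length(corpus)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr * config$lr_decay^(epoch - 1L)
    ord <- rng$sample(n)
    losses <- numeric(n)
    b0 <- 1L
    while (b0 <= n) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      acc <- NULL
      for (j in batch) {
        fw <- instance_forward(model, corpus[[j]], train = TRUE, rng = rng)
        if (!is.finite(fw$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               ", instance ", corpus[[j]]$id, call. = FALSE)
        losses[j] <- fw$loss
        acc <- grads_add(acc, instance_backward(model, fw))
      }
      g <- grads_scale(acc, 1 / length(batch))
      if (config$clip > 0) {
        gn <- sqrt(sum(params_flatten(g)^2))
        if (gn > config$clip) g <- grads_scale(g, config$clip / gn)
      }
      if (config$momentum > 0) {
        velocity <- if (is.null(velocity)) g
                    else grads_add(grads_scale(velocity, config$momentum), g)
        g <- velocity
      }
      model$params <- params_axpy(model$params, g, -lr)
      b0 <- b0 + config$batch_size
    }
    ev <- evaluate(model, dev, null_label = labels$null_label)
    metric <- if (is.null(labels$null_label) || is.na(ev$micro_f1))
      ev$accuracy else ev$micro_f1
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = mean(losses),
                                 dev_accuracy = ev$accuracy,
                                 dev_metric = metric))
    if (verbose)
      message(sprintf("epoch %3d  lr %.4f  loss %.4f  dev acc %.3f  dev metric %.3f",
                      epoch, lr, mean(losses), ev$accuracy, metric))
    if (metric > best$metric + 1e-12) {
      best <- list(metric = metric, params = model$params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$params <- best$params
  model$log <- log
  model$best_epoch <- best$epoch
  model$dev_metric <- best$metric
  model$call <- match.call()
  model
}

#' Predict relation labels
#'
#' @param object a fitted `"relgcn"` model.
#' @param newdata a [relation_instance] or list of them.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... unused.
#' @return character vector of labels, or an instances x labels probability
#'   matrix.
#' @export
predict.relgcn <- function(object, newdata,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "relation_instance")) newdata <- list(newdata)
  probs <- t(vapply(newdata, function(x)
    instance_forward(object, x, train = FALSE)$probs,
    numeric(length(object$label_set$labels))))
  colnames(probs) <- object$label_set$labels
  if (type == "prob") return(probs)
  object$label_set$labels[max.col(probs, ties.method = "first")]
}

#' @export
print.relgcn <- function(x, ...) {
  cfg <- x$config
  cat("Syntax-enhanced GCN relation classifier\n")
  cat(sprintf("  encoder : ON-LSTM d=%d (chunks of %d)%s\n", cfg$hidden_dim,
              cfg$chunk_size, if (cfg$bidirectional) ", bidirectional" else ""))
  cat(sprintf("  graph   : %d attention head(s), %d GCN layer(s)%s\n",
              cfg$heads, cfg$gcn_layers,
              if (cfg$use_pruning) sprintf(", %dx%d Gaussian equalization",
                                           cfg$kernel_size, cfg$kernel_size)
              else ", no equalization"))
  if (!cfg$use_feature_capture)
    cat("  (feature capture ablated: processor is the identity)\n")
  cat(sprintf("  labels  : %s\n", paste(x$label_set$labels, collapse = ", ")))
  if (!is.null(x$log) && nrow(x$log))
    cat(sprintf("  trained %d epoch(s); best dev metric %.3f at epoch %d\n",
                nrow(x$log), x$dev_metric, x$best_epoch))
  invisible(x)
}

#' @export
summary.relgcn <- function(object, ...) {
  print(object)
  np <- length(params_flatten(object$params))
  cat(sprintf("  parameters: %d trainable values; vocabulary %d tokens\n",
              np, length(object$vocab$index)))
  if (!is.null(object$log) && nrow(object$log)) {
    cat("  training log (last epochs):\n")
    print(utils::tail(object$log, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.relgcn <- function(object, ...) object$params

#' @export
plot.relgcn <- function(x, ...) {
  if (is.null(x$log) || !nrow(x$log))
    stop("no training log to plot", call. = FALSE)
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(x$log$epoch, x$log$train_loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean training loss",
       main = "training trajectory", ...)
  graphics::par(new = TRUE)
  plot(x$log$epoch, x$log$dev_metric, type = "b", pch = 1, lty = 2,
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1), col = "grey40")
  graphics::axis(4, col.axis = "grey40")
  graphics::mtext("dev metric", side = 4, line = 2.5, col = "grey40")
  invisible(x)
}

#' Cross-validate the model
#'
#' Seeded k-fold split of the corpus; each fold is held out for testing while
#' the model trains on the rest (with its own internal dev split for early
#' stopping). Reports the per-fold and mean test accuracy, the convention
#' used for cross-sentence evaluation.
#'
#' @param corpus list of [relation_instance] objects (size >= `folds`).
#' @param folds number of folds.
#' @param config a [relgcn_config].
#' @param ... passed on to [relgcn].
#' @return an object of class `"relgcn_cv"` with `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, and the fold assignment.
#' @export
crossvalidate <- function(corpus, folds = 5L, config = relgcn_config(), ...) {
  n <- length(corpus)
  if (folds > n) stop("more folds (", folds, ") than instances (", n, ")",
                      call. = FALSE)
  rng <- local_rng(config$seed * 7L + 41L)
  assignment <- rng$sample(rep_len(seq_len(folds), n))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    test <- corpus[assignment == k]
    train <- corpus[assignment != k]
    fit <- relgcn(train, config = config, ...)
    ev <- evaluate(fit, test, null_label = fit$label_set$null_label)
    acc[k] <- ev$accuracy
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), assignment = assignment,
                 folds = folds),
            class = "relgcn_cv")
}

#' @export
print.relgcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean accuracy %.3f (sd %.3f)\n",
              x$folds, x$mean_accuracy, x$sd_accuracy))
  cat("  per fold:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "),
      "\n")
  invisible(x)
}
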