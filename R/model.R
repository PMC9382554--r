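#' Model configuration
#'
#' Every hyperparameter and ablation toggle of the syntax-enhanced GCN in one
#' serializable object. Defaults follow the published setting where one is
#' stated (300-dimensional embeddings and hidden states, SGD with a 0.9
#' per-epoch learning-rate decay); the rest are the package's own defaults,
#' documented in the methods vignette.
#'
#' @param embedding_dim word-vector dimension.
#' @param hidden_dim ON-LSTM hidden size `d`.
#' @param chunk_size master-gate chunk width (divides `hidden_dim`).
#' @param heads number of attention heads.
#' @param gcn_layers GCN layers per head.
#' @param gcn_dim GCN layer width (default: encoder output dimension).
#' @param proc_dim processor output dimension D' (default: encoder output
#'   dimension).
#' @param kernel_size,kernel_sigma Gaussian equalization kernel (odd size;
#'   normalized, so the amplitude cancels).
#' @param dropout dropout probability on embeddings and encoder output.
#' @param lr,lr_decay,momentum SGD settings; the learning rate is multiplied
#'   by `lr_decay` after every epoch.
#' @param epochs,batch_size,patience training-loop settings; early stopping
#'   monitors the dev metric with this patience.
#' @param clip global gradient-norm clipping threshold (0 disables); the
#'   usual stabilizer for recurrent networks under plain SGD.
#' @param seed integer seed covering initialization, shuffling, dropout and
#'   data splits.
#' @param use_pruning,use_feature_capture ablation switches (see
#'   [feature_process]).
#' @param residual shortcut connection from the encoder output around the
#'   feature processor (requires `proc_dim` equal to the encoder output
#'   dimension); see [feature_process].
#' @param bidirectional add a reversed encoder pass (doubles the encoder
#'   output dimension).
#' @param task `"binary"`, `"multiclass"` (both two-entity) or `"ternary"`
#'   (three entities; the classifier consumes a fourth pooled vector).
#' @param pooling `"max"` or `"mean"` entity/sentence pooling.
#' @param activation GCN activation.
#' @param attn_full_dim give each head the full dimension instead of
#'   `D / heads`.
#' @param mask_entities replace entity mentions with role placeholder tokens.
#' @return an object of class `"relgcn_config"`.
#' @export
relgcn_config <- function(embedding_dim = 300L, hidden_dim = 300L,
                          chunk_size = 10L, heads = 4L, gcn_layers = 2L,
                          gcn_dim = NULL, proc_dim = NULL,
                          kernel_size = 3L, kernel_sigma = 1,
                          dropout = 0.5, lr = 0.1, lr_decay = 0.9,
                          momentum = 0, epochs = 30L, batch_size = 1L,
                          patience = 5L, clip = 5, seed = 1L,
                          use_pruning = TRUE, use_feature_capture = TRUE,
                          residual = TRUE, bidirectional = FALSE,
                          task = c("binary", "multiclass", "ternary"),
                          pooling = c("max", "mean"),
                          activation = "relu",
                          attn_full_dim = FALSE,
                          mask_entities = FALSE) {
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              hidden_dim = as.integer(hidden_dim),
              chunk_size = as.integer(chunk_size),
              heads = as.integer(heads),
              gcn_layers = as.integer(gcn_layers),
              gcn_dim = if (!is.null(gcn_dim)) as.integer(gcn_dim),
              proc_dim = if (!is.null(proc_dim)) as.integer(proc_dim),
              kernel_size = as.integer(kernel_size),
              kernel_sigma = as.numeric(kernel_sigma),
              dropout = as.numeric(dropout), lr = as.numeric(lr),
              lr_decay = as.numeric(lr_decay),
              momentum = as.numeric(momentum), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              patience = as.integer(patience), clip = as.numeric(clip),
              seed = as.integer(seed),
              use_pruning = isTRUE(use_pruning),
              use_feature_capture = isTRUE(use_feature_capture),
              residual = isTRUE(residual),
              bidirectional = isTRUE(bidirectional),
              task = task, pooling = pooling, activation = activation,
              attn_full_dim = isTRUE(attn_full_dim),
              mask_entities = isTRUE(mask_entities))
  validate_config(cfg)
  structure(cfg, class = "relgcn_config")
}

validate_config <- function(cfg) {
  pos <- c("embedding_dim", "hidden_dim", "chunk_size", "heads", "gcn_layers",
           "epochs", "batch_size", "patience")
  for (f in pos) if (cfg[[f]] < 1)
    stop(f, " must be positive", call. = FALSE)
  if (cfg$hidden_dim %% cfg$chunk_size != 0)
    stop("chunk_size must divide hidden_dim", call. = FALSE)
  if (cfg$lr_decay <= 0 || cfg$lr_decay > 1)
    stop("lr_decay must lie in (0, 1]", call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (cfg$kernel_size %% 2 == 0) stop("kernel_size must be odd", call. = FALSE)
  if (cfg$clip < 0) stop("clip must be non-negative", call. = FALSE)
  if (cfg$residual && cfg$use_feature_capture) {
    D <- cfg$hidden_dim * (1L + cfg$bidirectional)
    if (!is.null(cfg$proc_dim) && cfg$proc_dim != D)
      stop("residual shortcut requires proc_dim equal to the encoder ",
           "output dimension (", D, ")", call. = FALSE)
  }
  if (!cfg$use_feature_capture && cfg$use_pruning)
    stop("contradictory ablation flags: use_pruning requires ",
         "use_feature_capture", call. = FALSE)
  D <- cfg$hidden_dim * (1L + cfg$bidirectional)
  if (!cfg$attn_full_dim && D %% cfg$heads != 0)
    stop("heads must divide the encoder output dimension (", D, ")",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.relgcn_config <- function(x, ...) {
  cat("<relgcn_config>\n")
  for (f in names(x)) if (!is.null(x[[f]]))
    cat(sprintf("  %-20s %s\n", f, paste(x[[f]], collapse = " ")))
  invisible(x)
}

#' Write / read a model configuration file
#'
#' Round-trip serialization of [relgcn_config]: YAML when the path ends in
#' `.yaml`/`.yml` (requires the yaml package), JSON otherwise.
#'
#' @param config a [relgcn_config].
#' @param path file path.
#' @return `read_config` returns a [relgcn_config].
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(relgcn_config, x)
}

derived_dims <- function(cfg) {
  D <- cfg$hidden_dim * (1L + cfg$bidirectional)
  dh <- if (cfg$attn_full_dim) D else D %/% cfg$heads
  Dg <- cfg$gcn_dim %||% D
  Dp <- if (!cfg$use_feature_capture) D else (cfg$proc_dim %||% D)
  nvec <- if (cfg$task == "ternary") 4L else 3L
  list(D = D, dh = dh, Dg = Dg, Dp = Dp, nvec = nvec)
}

model_init <- function(config, vocab, labels) {
  if (vocab$dim != config$embedding_dim)
    stop("vocabulary dimension (", vocab$dim, ") != embedding_dim (",
         config$embedding_dim, ")", call. = FALSE)
  dd <- derived_dims(config)
  rng <- local_rng(config$seed * 7L + 3L)
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(rng$runif(nr * nc, -r, r), nr, nc)
  }
  e <- config$embedding_dim
  proc <- NULL
  if (config$use_feature_capture) {
    attn <- lapply(seq_len(config$heads), function(k)
      list(Wq = glorot(dd$D, dd$dh), Wk = glorot(dd$D, dd$dh)))
    gcn <- lapply(seq_len(config$heads), function(k) {
      lapply(seq_len(config$gcn_layers), function(l)
        if (l == 1) glorot(dd$D, dd$Dg) else glorot(dd$Dg, dd$Dg))
    })
    mix <- list(W = glorot(config$heads * dd$Dg, dd$Dp), b = numeric(dd$Dp))
    proc <- list(attn = attn, gcn = gcn, mix = mix)
  }
  params <- list(
    enc = onlstm_params(e, config$hidden_dim, config$chunk_size,
                        seed = config$seed * 7L + 11L),
    enc_bw = if (config$bidirectional)
      onlstm_params(e, config$hidden_dim, config$chunk_size,
                    seed = config$seed * 7L + 13L),
    proc = proc,
    clf = classifier_params(dd$nvec * dd$Dp, dd$Dp, length(labels$labels),
                            seed = config$seed * 7L + 17L))
  kernel <- build_gaussian_kernel(gaussian_kernel_spec(
    size = config$kernel_size,
    sigma = rep(config$kernel_sigma, 2), normalize = TRUE))
  structure(list(params = params, config = config, vocab = vocab,
                 label_set = labels, kernel = kernel, dims = dd),
            class = "relgcn")
}

instance_forward <- function(model, inst, train = FALSE, rng = NULL) {
  cfg <- model$config
  if (cfg$mask_entities) inst <- mask_entities(inst)
  n <- length(inst$tokens)
  X <- embed_tokens(model$vocab, inst$tokens)
  drop_x <- drop_h <- NULL
  if (train && cfg$dropout > 0) {
    drop_x <- matrix((rng$runif(n * ncol(X)) >= cfg$dropout) /
                       (1 - cfg$dropout), n, ncol(X))
    X <- X * drop_x
  }
  enc <- onlstm_encode(X, model$params$enc, model$params$enc_bw)
  h <- enc$h
  if (train && cfg$dropout > 0) {
    drop_h <- matrix((rng$runif(length(h)) >= cfg$dropout) /
                       (1 - cfg$dropout), nrow(h), ncol(h))
    h <- h * drop_h
  }
  proc <- if (cfg$use_feature_capture)
    feature_process_forward(h, model$params$proc, model$kernel,
                            cfg$use_pruning, TRUE, cfg$activation,
                            residual = cfg$residual)
  else list(out = h, identity = TRUE)
  Hp <- proc$out
  pools <- list(
    sent = pool_forward(Hp, type = cfg$pooling),
    s = pool_forward(Hp, span = inst$entities$subject, type = cfg$pooling),
    o = pool_forward(Hp, span = inst$entities$object, type = cfg$pooling))
  if (cfg$task == "ternary") {
    if (is.null(inst$entities$third))
      stop("ternary task requires a third entity span (instance ",
           inst$id, ")", call. = FALSE)
    pools$third <- pool_forward(Hp, span = inst$entities$third,
                                type = cfg$pooling)
  }
  clf_in <- list(H_sent = pools$sent$v, H_s = pools$s$v, H_o = pools$o$v,
                 H_third = if (!is.null(pools$third)) pools$third$v)
  clf <- classifier_forward(clf_in, model$params$clf)
  gold <- match(inst$label, model$label_set$labels)
  loss <- if (is.na(gold)) NA_real_ else -log(max(clf$p[gold], 1e-12))
  list(loss = loss, probs = stats::setNames(clf$p, model$label_set$labels),
       gold = gold, enc = enc, proc = proc, pools = pools, clf = clf,
       drop_h = drop_h, n = n, Hp_dim = ncol(Hp), inst = inst)
}

instance_backward <- function(model, fw) {
  cfg <- model$config
  y <- numeric(length(fw$probs)); y[fw$gold] <- 1
  dlogits <- unname(fw$probs) - y
  cb <- classifier_backward(fw$clf, dlogits, model$params$clf)
  Dp <- fw$Hp_dim
  dHp <- pool_backward(fw$pools$sent, cb$dv[seq_len(Dp)], fw$n, Dp) +
    pool_backward(fw$pools$s, cb$dv[Dp + seq_len(Dp)], fw$n, Dp) +
    pool_backward(fw$pools$o, cb$dv[2 * Dp + seq_len(Dp)], fw$n, Dp)
  if (!is.null(fw$pools$third))
    dHp <- dHp + pool_backward(fw$pools$third, cb$dv[3 * Dp + seq_len(Dp)],
                               fw$n, Dp)
  pb <- feature_process_backward(fw$proc, dHp, model$params$proc)
  dh <- pb$dh
  if (!is.null(fw$drop_h)) dh <- dh * fw$drop_h
  eb <- onlstm_encode_backward(fw$enc, dh, model$params$enc,
                               model$params$enc_bw)
  list(enc = eb$grads, enc_bw = eb$grads_bw, proc = pb$grads, clf = cb$grads)
}

# ---- parameter-tree utilities (flatten / update over double leaves) --------

params_flatten <- function(x) {
  if (is.list(x)) return(unlist(lapply(x, params_flatten), use.names = FALSE))
  if (is.double(x)) return(as.numeric(x))
  numeric(0)
}

params_unflatten <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    if (is.double(x)) {
      k <- length(x)
      out <- vec[pos + seq_len(k)]
      pos <<- pos + k
      if (is.matrix(x)) dim(out) <- dim(x)
      return(out)
    }
    x
  }
  out <- fill(skeleton)
  stopifnot(pos == length(vec))
  # restore classes on known components
  preserve_attrs(out, skeleton)
}

preserve_attrs <- function(x, skel) {
  if (is.list(x) && is.list(skel)) {
    x <- mapply(preserve_attrs, x, skel, SIMPLIFY = FALSE)
    attributes(x) <- attributes(skel)
  }
  x
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, s = s))
  if (!is.double(g)) return(g)     # integer metadata leaves pass through
  g * s
}

# p <- p + a * g, walking the grad tree (metadata leaves untouched)
params_axpy <- function(p, g, a) {
  if (is.null(g)) return(p)
  if (is.list(g)) {
    idx <- if (is.null(names(g))) seq_along(g) else names(g)
    for (nm in idx) p[[nm]] <- params_axpy(p[[nm]], g[[nm]], a)
    return(p)
  }
  p + a * g
}

total_loss_fn <- function(model, instances) {
  function(theta) {
    m <- model
    m$params <- params_unflatten(theta, model$params)
    sum(vapply(instances, function(x)
      instance_forward(m, x, train = FALSE)$loss, numeric(1)))
  }
}

total_grad <- function(model, instances) {
  g <- NULL
  for (x in instances) {
    fw <- instance_forward(model, x, train = FALSE)
    g <- grads_add(g, instance_backward(model, fw))
  }
  g
}
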