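#' Classification metrics for relation extraction
#'
#' Computes the confusion matrix, accuracy, per-class precision/recall/F1,
#' and micro-F1 pooled over the non-null classes (the standard convention:
#' true positives, false positives and false negatives are summed over every
#' positive relation class, excluding the no-relation label from the positive
#' set; predicting null everywhere therefore scores 0).
#'
#' @param pred,gold character vectors of predicted and gold labels.
#' @param labels character vector of all labels (fixes the confusion-matrix
#'   order).
#' @param null_label optional no-relation label excluded from micro-F1.
#' @return an object of class `"relgcn_eval"`: `accuracy`, `confusion`
#'   (gold rows x predicted columns), `per_class` data frame, `micro_f1`,
#'   `n`.
#' @export
relation_metrics <- function(pred, gold, labels = sort(unique(c(pred, gold))),
                             null_label = NULL) {
  if (length(pred) != length(gold))
    stop("pred and gold lengths differ", call. = FALSE)
  if (!length(gold)) stop("empty evaluation set", call. = FALSE)
  pred <- factor(pred, levels = labels)
  gold <- factor(gold, levels = labels)
  conf <- table(gold = gold, pred = pred)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & prec + rec > 0,
               2 * prec * rec / (prec + rec), ifelse(tp + fp + fn > 0, 0, NA_real_))
  per_class <- data.frame(label = labels, support = as.numeric(rowSums(conf)),
                          precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1))
  pos <- if (is.null(null_label)) labels else setdiff(labels, null_label)
  TP <- sum(tp[pos]); FP <- sum(fp[pos]); FN <- sum(fn[pos])
  micro_p <- if (TP + FP > 0) TP / (TP + FP) else 0
  micro_r <- if (TP + FN > 0) TP / (TP + FN) else 0
  micro_f1 <- if (micro_p + micro_r > 0)
    2 * micro_p * micro_r / (micro_p + micro_r) else 0
  structure(list(accuracy = mean(pred == gold), confusion = conf,
                 per_class = per_class, micro_precision = micro_p,
                 micro_recall = micro_r, micro_f1 = micro_f1,
                 null_label = null_label, n = length(gold)),
            class = "relgcn_eval")
}

#' @export
print.relgcn_eval <- function(x, ...) {
  cat(sprintf("relation-extraction evaluation on %d instances\n", x$n))
  cat(sprintf("  accuracy  %.4f\n", x$accuracy))
  cat(sprintf("  micro-F1  %.4f (precision %.4f, recall %.4f%s)\n",
              x$micro_f1, x$micro_precision, x$micro_recall,
              if (!is.null(x$null_label))
                paste0("; null class '", x$null_label, "' excluded") else ""))
  cat("  per class:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate a fitted model on a corpus
#'
#' @param model a fitted `"relgcn"` model.
#' @param corpus list of [relation_instance] objects.
#' @param null_label no-relation label excluded from micro-F1 (defaults to
#'   the model's label set).
#' @return a `"relgcn_eval"` object (see [relation_metrics]).
#' @export
evaluate <- function(model, corpus, null_label = model$label_set$null_label) {
  if (!length(corpus)) stop("empty evaluation corpus", call. = FALSE)
  gold <- vapply(corpus, `[[`, character(1), "label")
  bad <- setdiff(unique(gold), model$label_set$labels)
  if (length(bad))
    stop("corpus labels absent from the model's label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  pred <- predict(model, corpus)
  relation_metrics(pred, gold, labels = model$label_set$labels,
                   null_label = null_label)
}

#' Length-stratified evaluation
#'
#' Splits a corpus into sentence-length bins (token counts, half-open
#' `[lo, hi)` intervals) and evaluates each bin separately. Longer passages
#' separate the entities further, so per-bin scores probe how well the model
#' captures nonlocal interactions.
#'
#' @param model a fitted `"relgcn"` model.
#' @param corpus list of [relation_instance] objects.
#' @param bins list of numeric pairs `(lo, hi)`; must cover every length in
#'   the corpus.
#' @return named list of `"relgcn_eval"` objects, one per non-empty bin
#'   (empty bins are reported as absent); names are `"[lo,hi)"`.
#' @export
length_stratified_eval <- function(model, corpus,
                                   bins = list(c(0, 25), c(25, 50),
                                               c(50, Inf))) {
  lens <- vapply(corpus, function(x) length(x$tokens), integer(1))
  which_bin <- vapply(lens, function(l) {
    hit <- which(vapply(bins, function(b) l >= b[1] && l < b[2], logical(1)))
    if (!length(hit)) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(which_bin))
    stop("bins do not cover sentence length(s): ",
         paste(unique(lens[is.na(which_bin)]), collapse = ", "),
         call. = FALSE)
  out <- list()
  for (k in seq_along(bins)) {
    members <- corpus[which_bin == k]
    if (!length(members)) next        # empty bin: absent, not zero
    nm <- sprintf("[%s,%s)", format(bins[[k]][1]), format(bins[[k]][2]))
    out[[nm]] <- evaluate(model, members)
  }
  out
}
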