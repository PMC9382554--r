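#' Specify a synthetic relation-extraction corpus
#'
#' Describes a corpus with a planted, fully learnable labeling rule: each
#' positive instance carries a label-specific trigger word strictly between
#' its two entity spans, while null instances carry none. A `noise_rate`
#' fraction of positive instances have their trigger removed (label kept), so
#' the best achievable accuracy of any classifier is bounded by the realized
#' clean fraction. Distractor triggers of other labels may appear *outside*
#' the entity-to-entity path, so position and structure -- not bag-of-words --
#' determine the label. Filler text is nested in bracketed phrases up to
#' `nesting_depth`, giving the encoder hierarchical structure to exploit.
#'
#' The defaults emulate a chemical-protein style multi-class corpus (five
#' positive relation types plus a null class); pass a binary `label_set` and a
#' one-entry `trigger_map` for a phenotype-gene style Yes/No corpus.
#'
#' @param n_instances number of instances to generate.
#' @param label_set a [label_set]; must have a `null_label` set.
#' @param vocab_size total token-type budget (filler + triggers + entity names
#'   + brackets); must leave at least 5 filler types.
#' @param length_range integer pair `(min, max)` of sentence lengths in
#'   tokens, inclusive; `min >= 5`.
#' @param trigger_map named list: label -> character vector of trigger words;
#'   every non-null label needs at least one trigger.
#' @param nesting_depth maximum depth of bracketed phrase nesting in filler.
#' @param noise_rate probability in `[0, 0.5)` that a positive instance's
#'   trigger is removed (label unchanged).
#' @param task `"binary"`/`"multiclass"` (two entities) or `"ternary"` (a
#'   third entity; the label requires its trigger on both entity-pair paths).
#' @param distractor_rate probability of inserting an off-path trigger.
#' @param seed integer seed; identical spec and seed give identical corpora.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_instances = 1000L,
                           label_set = relgcn::label_set(
                             c("None", "CPR:2", "CPR:3", "CPR:4", "CPR:5", "CPR:6"),
                             null_label = "None"),
                           vocab_size = 120L,
                           length_range = c(8L, 40L),
                           trigger_map = list(
                             "CPR:2" = "agonist",
                             "CPR:3" = "upregulates",
                             "CPR:4" = "downregulates",
                             "CPR:5" = "substrate",
                             "CPR:6" = "antagonist"),
                           nesting_depth = 2L,
                           noise_rate = 0,
                           task = c("multiclass", "binary", "ternary"),
                           distractor_rate = 0.5,
                           seed = 1L) {
  task <- match.arg(task)
  if (is.null(label_set$null_label))
    stop("synthetic corpora require a null_label in the label set",
         call. = FALSE)
  pos <- setdiff(label_set$labels, label_set$null_label)
  missing_triggers <- pos[!vapply(pos, function(l)
    length(trigger_map[[l]]) >= 1, logical(1))]
  if (length(missing_triggers))
    stop("every non-null label needs at least one trigger word; missing: ",
         paste(missing_triggers, collapse = ", "), call. = FALSE)
  length_range <- as.integer(length_range)
  if (length_range[1] < 5L)
    stop("minimum sentence length must be at least 5", call. = FALSE)
  if (length_range[2] < length_range[1])
    stop("length_range must be non-decreasing", call. = FALSE)
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop("noise_rate must lie in [0, 0.5)", call. = FALSE)
  triggers <- unique(unlist(trigger_map, use.names = FALSE))
  n_entity_pool <- 20L
  n_filler <- as.integer(vocab_size) - length(triggers) - n_entity_pool - 2L
  if (n_filler < 5L)
    stop("vocab_size too small: need at least ",
         length(triggers) + n_entity_pool + 2L + 5L,
         " token types to host all triggers, entities, brackets and filler",
         call. = FALSE)
  structure(list(
    n_instances = as.integer(n_instances),
    label_set = label_set,
    vocab_size = as.integer(vocab_size),
    length_range = length_range,
    trigger_map = trigger_map,
    nesting_depth = as.integer(nesting_depth),
    noise_rate = noise_rate,
    task = task,
    distractor_rate = distractor_rate,
    seed = as.integer(seed),
    entity_pool = sprintf("ent%02d", seq_len(n_entity_pool)),
    filler_pool = sprintf("w%03d", seq_len(n_filler))),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_instances, " instances, task ", x$task,
      ", labels {", paste(x$label_set$labels, collapse = ", "),
      "}, lengths [", x$length_range[1], ",", x$length_range[2],
      "], noise ", x$noise_rate, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# filler text with nested bracketed phrases up to `depth`
gen_filler <- function(len, depth, pool, rng) {
  if (len <= 0) return(character(0))
  if (depth > 0 && len >= 4 && rng$runif(1) < 0.4) {
    inner_len <- rng$sample_int(len - 2L, 1L)
    pre_len <- rng$sample_int(len - inner_len - 1L, 1L) - 1L
    c(gen_filler(pre_len, depth, pool, rng),
      "(", gen_filler(inner_len, depth - 1L, pool, rng), ")",
      gen_filler(len - pre_len - inner_len - 2L, depth, pool, rng))
  } else {
    pool[rng$sample_int(length(pool), len, replace = TRUE)]
  }
}

gen_one_instance <- function(spec, id, target_len, rng) {
  ls <- spec$label_set
  labels <- ls$labels
  label <- labels[rng$sample_int(length(labels), 1L)]
  is_null <- identical(label, ls$null_label)
  n_ent <- if (spec$task == "ternary") 3L else 2L
  ent_tokens <- spec$entity_pool[rng$sample_int(length(spec$entity_pool), n_ent)]
  n_gaps <- n_ent + 1L            # before e1, between pairs, after last
  budget <- target_len - n_ent
  # each inter-entity gap needs >= 1 token (room for a trigger on the path)
  gap_min <- c(0L, rep(1L, n_ent - 1L), 0L)
  free <- budget - sum(gap_min)
  extra <- gap_min + tabulate(rng$sample_int(n_gaps, free, replace = TRUE),
                              nbins = n_gaps)
  gaps <- lapply(extra, function(g)
    gen_filler(g, spec$nesting_depth, spec$filler_pool, rng))

  corrupted <- FALSE
  if (!is_null) {
    trig_pool <- spec$trigger_map[[label]]
    trig <- trig_pool[rng$sample_int(length(trig_pool), 1L)]
    if (rng$runif(1) < spec$noise_rate) {
      corrupted <- TRUE                      # trigger withheld, label kept
    } else {
      # plant the trigger on every inter-entity path the task inspects
      for (g in 2:(n_gaps - 1L)) {
        seg <- gaps[[g]]
        pos <- rng$sample_int(length(seg), 1L)
        gaps[[g]] <- append(seg, trig, after = pos - 1L)
      }
    }
  }
  if (rng$runif(1) < spec$distractor_rate) {
    # off-path trigger of a random label, in the prefix or suffix
    all_trigs <- unlist(spec$trigger_map, use.names = FALSE)
    d_trig <- all_trigs[rng$sample_int(length(all_trigs), 1L)]
    side <- if (rng$runif(1) < 0.5) 1L else n_gaps
    seg <- gaps[[side]]
    pos <- if (length(seg)) rng$sample_int(length(seg) + 1L, 1L) - 1L else 0L
    gaps[[side]] <- append(seg, d_trig, after = pos)
  }

  tokens <- gaps[[1]]
  spans0 <- integer(n_ent)                   # 0-based start of each entity
  for (k in seq_len(n_ent)) {
    spans0[k] <- length(tokens)
    tokens <- c(tokens, ent_tokens[k], gaps[[k + 1L]])
  }
  roles <- if (n_ent == 3L) c("subject", "object", "third") else c("subject", "object")
  if (rng$runif(1) < 0.5 && n_ent == 2L) roles <- rev(roles)  # object may precede subject
  ents <- stats::setNames(
    lapply(spans0, function(s) c(s, s + 1L)), roles)
  inst <- relation_instance(tokens, ents, label, id = id)
  attr(inst, "corrupted") <- corrupted
  inst
}

#' Generate a synthetic relation-extraction corpus
#'
#' Draws `spec$n_instances` instances under the planted trigger rule described
#' in [synthetic_spec]. The returned list carries a logical attribute
#' `"corrupted"` flagging the noise-corrupted positives (trigger withheld).
#'
#' @param spec a [synthetic_spec].
#' @return list of [relation_instance] objects.
#' @seealso [trigger_rule_predict] for the oracle that inverts the rule.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- local_rng(spec$seed)
  lens <- spec$length_range[1] +
    rng$sample_int(spec$length_range[2] - spec$length_range[1] + 1L,
                   spec$n_instances, replace = TRUE) - 1L
  out <- vector("list", spec$n_instances)
  for (i in seq_len(spec$n_instances))
    out[[i]] <- gen_one_instance(spec, sprintf("syn%05d", i), lens[i], rng)
  attr(out, "corrupted") <- vapply(out, function(x)
    isTRUE(attr(x, "corrupted")), logical(1))
  out
}

#' Generate a corpus with a controlled sentence-length distribution
#'
#' Splits `n_instances` equally (within one) across disjoint length bins
#' `[lo, hi)` and samples each instance's length uniformly inside its bin,
#' intersected with the spec's `length_range`. Used for length-stratified
#' evaluation, where longer sentences place the trigger further from the
#' entities and stress nonlocal interactions.
#'
#' @param spec a [synthetic_spec].
#' @param bins list of numeric pairs `(lo, hi)`, half-open, disjoint.
#' @return list of [relation_instance] objects, with a `"corrupted"` attribute.
#' @export
generate_length_stratified <- function(spec, bins) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (b in bins) if (b[2] <= b[1])
    stop("each bin must satisfy lo < hi", call. = FALSE)
  if (length(bins) > 1) {
    ord <- order(vapply(bins, `[`, numeric(1), 1))
    sb <- bins[ord]
    for (k in seq_len(length(sb) - 1))
      if (sb[[k + 1]][1] < sb[[k]][2])
        stop("bins must be disjoint", call. = FALSE)
  }
  ranges <- lapply(bins, function(b) {
    lo <- max(ceiling(b[1]), spec$length_range[1])
    hi <- min(floor(b[2] - 1), spec$length_range[2])
    if (hi < lo)
      stop("bin [", b[1], ",", b[2], ") infeasible given length_range [",
           spec$length_range[1], ",", spec$length_range[2], "]", call. = FALSE)
    c(lo, hi)
  })
  n <- spec$n_instances
  base <- n %/% length(bins)
  counts <- rep(base, length(bins))
  if (n %% length(bins) > 0)
    counts[seq_len(n %% length(bins))] <- base + 1L
  rng <- local_rng(spec$seed)
  out <- vector("list", n)
  i <- 0L
  for (k in seq_along(bins)) {
    r <- ranges[[k]]
    for (j in seq_len(counts[k])) {
      len <- r[1] + rng$sample_int(r[2] - r[1] + 1L, 1L) - 1L
      i <- i + 1L
      out[[i]] <- gen_one_instance(spec, sprintf("syn%05d", i), len, rng)
    }
  }
  attr(out, "corrupted") <- vapply(out, function(x)
    isTRUE(attr(x, "corrupted")), logical(1))
  out
}

#' Predict labels by the planted trigger rule
#'
#' The rule oracle that inverts the synthetic generator: scan the tokens
#' strictly between the subject and object spans (and, for ternary instances,
#' also between object and third entity); the first label whose trigger
#' appears on the path (on *both* paths for ternary) is predicted, otherwise
#' the null label. On a noise-free corpus this recovers every label; with
#' noise it errs exactly on the corrupted positives, so its accuracy is the
#' Bayes ceiling for any classifier trained on the same corpus.
#'
#' @param instances a [relation_instance] or list of them.
#' @param trigger_map named list label -> trigger words.
#' @param null_label the no-relation label.
#' @return character vector of predicted labels.
#' @export
trigger_rule_predict <- function(instances, trigger_map, null_label) {
  if (inherits(instances, "relation_instance")) instances <- list(instances)
  vapply(instances, function(x) {
    sp <- x$entities[order(vapply(x$entities, `[[`, integer(1), 1))]
    paths <- lapply(seq_len(length(sp) - 1L), function(k) {
      from <- sp[[k]][2]; to <- sp[[k + 1L]][1]
      if (to > from) x$tokens[(from + 1):to] else character(0)
    })
    for (lab in names(trigger_map)) {
      hit <- vapply(paths, function(p)
        any(p %in% trigger_map[[lab]]), logical(1))
      if (all(hit)) return(lab)
    }
    null_label
  }, character(1))
}
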