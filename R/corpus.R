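#' Construct a relation-extraction instance
#'
#' A `relation_instance` is the atomic supervised example: a pre-tokenized
#' sentence (or concatenated multi-sentence passage), entity spans marking the
#' subject and object mentions (optionally a third entity for ternary
#' cross-sentence tasks), and a categorical relation label.
#'
#' Spans are 0-based, half-open `[start, end)` over the token list. Roles are
#' unique per instance: at most one subject, one object, one third entity.
#'
#' @param tokens character vector of word tokens (pre-tokenized input).
#' @param entities named list of integer pairs `c(start, end)`; names are roles
#'   from `"subject"`, `"object"`, `"third"`.
#' @param label character scalar relation label.
#' @param id instance identifier string.
#' @return an object of class `"relation_instance"`.
#' @examples
#' relation_instance(c("TP53", "binds", "MDM2"),
#'                   list(subject = c(0L, 1L), object = c(2L, 3L)),
#'                   label = "Yes", id = "ex1")
#' @export
relation_instance <- function(tokens, entities, label, id = "") {
  x <- structure(
    list(id = as.character(id),
         tokens = as.character(tokens),
         entities = lapply(entities, function(sp) as.integer(sp[1:2])),
         label = as.character(label)),
    class = "relation_instance")
  validate_instance(x)
  x
}

validate_instance <- function(x, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  n <- length(x$tokens)
  roles <- names(x$entities)
  if (is.null(roles) || any(!nzchar(roles)))
    stop("entity spans must be named by role", where, call. = FALSE)
  bad <- setdiff(roles, c("subject", "object", "third"))
  if (length(bad))
    stop("unknown entity role(s): ", paste(bad, collapse = ", "), where,
         call. = FALSE)
  if (anyDuplicated(roles))
    stop("duplicate entity role", where, call. = FALSE)
  for (r in roles) {
    sp <- x$entities[[r]]
    if (length(sp) != 2 || anyNA(sp))
      stop("span for role '", r, "' must be two integers", where, call. = FALSE)
    if (!(sp[1] >= 0 && sp[1] < sp[2] && sp[2] <= n))
      stop("span for role '", r, "' out of range: [", sp[1], ",", sp[2],
           ") on ", n, " tokens", where, call. = FALSE)
  }
  if (!all(c("subject", "object") %in% roles))
    stop("instance requires both a subject and an object span", where,
         call. = FALSE)
  if (length(x$label) != 1 || is.na(x$label) || !nzchar(x$label))
    stop("label must be a non-empty string", where, call. = FALSE)
  invisible(x)
}

#' @export
print.relation_instance <- function(x, ...) {
  cat("<relation_instance ", x$id, ">  label: ", x$label, "\n", sep = "")
  cat("  ", paste(x$tokens, collapse = " "), "\n", sep = "")
  for (r in names(x$entities)) {
    sp <- x$entities[[r]]
    cat("  ", r, ": [", sp[1], ",", sp[2], ") \"",
        paste(x$tokens[(sp[1] + 1):sp[2]], collapse = " "), "\"\n", sep = "")
  }
  invisible(x)
}

#' Define a label set
#'
#' The ordered set of relation labels a corpus uses, optionally designating a
#' null ("no relation") class. Binary phenotype-gene style corpora use
#' `c("No", "Yes")` with `null_label = "No"`; multi-class chemical-protein
#' style corpora use e.g. `c("None", "CPR:2", ..., "CPR:6")` with
#' `null_label = "None"`.
#'
#' @param labels character vector of unique label strings.
#' @param null_label optional member of `labels` marking the no-relation class;
#'   excluded from the positive set when computing micro-F1.
#' @return an object of class `"label_set"`.
#' @export
label_set <- function(labels, null_label = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (!is.null(null_label) && !null_label %in% labels)
    stop("null_label must be a member of labels", call. = FALSE)
  structure(list(labels = labels, null_label = null_label),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set> ", paste(x$labels, collapse = ", "), sep = "")
  if (!is.null(x$null_label)) cat("  (null: ", x$null_label, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a relation-extraction corpus
#'
#' Reads instances from either a JSON-lines file (one JSON object per line with
#' keys `id`, `tokens`, `entities`, `label`; each entity an object with `role`,
#' `start`, `end`) or a TSV dialect (columns `id`, `label`, space-joined
#' tokens, space-joined `role:start:end` triples). Spans are 0-based half-open
#' in both formats.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return list of [relation_instance] objects, in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- if (format == "jsonl") parse_jsonl_record(lines[[i]], i)
           else parse_tsv_record(lines[[i]], i)
    validate_instance(rec, line = i)
    out[[i]] <- rec
  }
  out
}

parse_jsonl_record <- function(line, lineno) {
  rec <- tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
                  error = function(e)
                    stop("line ", lineno, ": malformed JSON: ",
                         conditionMessage(e), call. = FALSE))
  for (field in c("tokens", "entities", "label"))
    if (is.null(rec[[field]]))
      stop("line ", lineno, ": missing field '", field, "'", call. = FALSE)
  ents <- list()
  for (e in rec$entities) {
    for (field in c("role", "start", "end"))
      if (is.null(e[[field]]))
        stop("line ", lineno, ": entity missing field '", field, "'",
             call. = FALSE)
    ents[[e$role]] <- c(as.integer(e$start), as.integer(e$end))
  }
  structure(list(id = as.character(rec$id %||% ""),
                 tokens = vapply(rec$tokens, as.character, character(1)),
                 entities = ents,
                 label = as.character(rec$label)),
            class = "relation_instance")
}

parse_tsv_record <- function(line, lineno) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 4)
    stop("line ", lineno, ": expected 4 tab-separated fields ",
         "(id, label, tokens, spans), got ", length(parts), call. = FALSE)
  tokens <- strsplit(parts[3], " ", fixed = TRUE)[[1]]
  ents <- list()
  for (triple in strsplit(parts[4], " ", fixed = TRUE)[[1]]) {
    bits <- strsplit(triple, ":", fixed = TRUE)[[1]]
    if (length(bits) != 3)
      stop("line ", lineno, ": malformed span triple '", triple,
           "' (want role:start:end)", call. = FALSE)
    ents[[bits[1]]] <- as.integer(bits[2:3])
  }
  structure(list(id = parts[1], tokens = tokens, entities = ents,
                 label = parts[2]),
            class = "relation_instance")
}

#' Write a relation-extraction corpus
#'
#' Inverse of [read_corpus]: `read_corpus(write_corpus(x, p), format)` returns
#' instances field-identical to `x`, for both formats. UTF-8 throughout.
#'
#' @param instances list of [relation_instance] objects.
#' @param path output file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @export
write_corpus <- function(instances, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  lines <- vapply(instances, function(x) {
    validate_instance(x)
    if (format == "jsonl") {
      ents <- lapply(names(x$entities), function(r)
        list(role = r, start = x$entities[[r]][1], end = x$entities[[r]][2]))
      jsonlite::toJSON(list(id = x$id, tokens = as.list(x$tokens),
                            entities = ents, label = x$label),
                       auto_unbox = TRUE)
    } else {
      triples <- vapply(names(x$entities), function(r)
        paste(r, x$entities[[r]][1], x$entities[[r]][2], sep = ":"),
        character(1))
      paste(x$id, x$label, paste(x$tokens, collapse = " "),
            paste(triples, collapse = " "), sep = "\t")
    }
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a vocabulary with an embedding matrix
#'
#' Collects every token type appearing in `instances` (lowercased before
#' lookup, matching the usual pretrained-vector convention), assigns indices
#' with two reserved slots -- `<pad>` (index 1, zero embedding) and `<unk>`
#' (index 2) -- and fills an embedding matrix. Tokens found in the pretrained
#' file get their pretrained vectors; all others (including `<unk>`) are drawn
#' i.i.d. uniform on `[-0.5/dim, 0.5/dim]` from a seeded generator, so the same
#' corpus and seed reproduce the matrix exactly.
#'
#' @param instances list of [relation_instance] objects.
#' @param embeddings_path optional path to a whitespace-separated text
#'   embedding file (`word v1 v2 ... vd`, one token per line, UTF-8).
#' @param dim embedding dimension; must match the file when one is given.
#' @param seed integer seed for the random rows.
#' @return an object of class `"relgcn_vocab"`: `index` (named integer vector
#'   token -> row), `embeddings` (|V| x dim matrix), `pad`, `unk` indices.
#' @export
build_vocabulary <- function(instances, embeddings_path = NULL, dim = 300L,
                             seed = 1L) {
  dim <- as.integer(dim)
  if (dim < 1) stop("dim must be positive", call. = FALSE)
  toks <- unique(tolower(unlist(lapply(instances, `[[`, "tokens"),
                                use.names = FALSE)))
  toks <- setdiff(toks, c("<pad>", "<unk>"))
  vocab <- c("<pad>", "<unk>", toks)
  index <- stats::setNames(seq_along(vocab), vocab)

  pre <- NULL
  if (!is.null(embeddings_path)) {
    pre <- read_embedding_file(embeddings_path)
    if (ncol(pre$vectors) != dim)
      stop("embedding file dimension (", ncol(pre$vectors),
           ") does not match dim (", dim, ")", call. = FALSE)
  }

  emb <- matrix(0, nrow = length(vocab), ncol = dim)
  rng <- local_rng(seed)
  # pad row stays zero; every other row gets a seeded init first so that the
  # draw sequence is independent of which tokens the pretrained file covers
  for (i in 2:length(vocab))
    emb[i, ] <- rng$runif(dim, -0.5 / dim, 0.5 / dim)
  if (!is.null(pre)) {
    hit <- intersect(vocab, pre$words)
    if (length(hit))
      emb[index[hit], ] <- pre$vectors[match(hit, pre$words), , drop = FALSE]
  }
  structure(list(index = index, embeddings = emb, pad = 1L, unk = 2L,
                 dim = dim, seed = as.integer(seed)),
            class = "relgcn_vocab")
}

read_embedding_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  words <- vapply(parts, `[[`, character(1), 1)
  d <- length(parts[[1]]) - 1L
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(vecs)) stop("non-numeric embedding values in ", path, call. = FALSE)
  list(words = words, vectors = vecs)
}

#' @export
print.relgcn_vocab <- function(x, ...) {
  cat("<relgcn_vocab> ", length(x$index), " tokens (incl. <pad>, <unk>), dim ",
      x$dim, "\n", sep = "")
  invisible(x)
}

#' Look up token embeddings for an instance
#'
#' Maps each token (lowercased) to its vocabulary row, falling back to the
#' shared `<unk>` row, and returns the n x dim embedding matrix.
#'
#' @param vocab a [build_vocabulary] result.
#' @param tokens character vector of tokens.
#' @return n x dim numeric matrix.
#' @export
embed_tokens <- function(vocab, tokens) {
  idx <- vocab$index[tolower(tokens)]
  idx[is.na(idx)] <- vocab$unk
  vocab$embeddings[idx, , drop = FALSE]
}

#' Write synthetic pretrained-style word vectors
#'
#' Generates a whitespace-separated text embedding file (`word v1 ... vd`,
#' the usual pretrained-vector format) with i.i.d. Gaussian entries at the
#' scale typical of published word vectors. Synthetic corpora have no real
#' pretrained embeddings, so training runs pair them with these synthetic
#' stand-ins; the draw is seeded and reproducible.
#'
#' @param tokens character vector of token types (lowercased on write).
#' @param path output file path.
#' @param dim embedding dimension.
#' @param seed integer seed.
#' @param sd entry standard deviation (default 0.4, the scale of typical
#'   pretrained vectors).
#' @return (invisibly) the path.
#' @export
write_random_embeddings <- function(tokens, path, dim = 300L, seed = 1L,
                                    sd = 0.4) {
  tokens <- unique(tolower(tokens))
  rng <- local_rng(seed)
  lines <- vapply(tokens, function(tok)
    paste(tok, paste(sprintf("%.6f", rng$rnorm(dim, 0, sd)), collapse = " ")),
    character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Replace entity mentions with role placeholder tokens
#'
#' Optional entity-masking preprocessing: tokens inside each entity span are
#' replaced by a single role token (`<subject>`, `<object>`, `<third>`), and
#' spans are remapped accordingly. Some relation-extraction pipelines mask
#' entities so the model cannot memorize mention strings; the switch is
#' exposed but off by default.
#'
#' @param instance a [relation_instance].
#' @return a new [relation_instance] with masked mentions.
#' @export
mask_entities <- function(instance) {
  ents <- instance$entities
  ord <- order(vapply(ents, `[[`, integer(1), 1))
  roles <- names(ents)[ord]
  tokens <- instance$tokens
  new_tokens <- character(0)
  new_ents <- list()
  cursor <- 0L  # 0-based position consumed so far
  for (r in roles) {
    sp <- ents[[r]]
    if (sp[1] > cursor)
      new_tokens <- c(new_tokens, tokens[(cursor + 1):sp[1]])
    start <- length(new_tokens)
    new_tokens <- c(new_tokens, paste0("<", r, ">"))
    new_ents[[r]] <- c(start, start + 1L)
    cursor <- sp[2]
  }
  if (cursor < length(tokens))
    new_tokens <- c(new_tokens, tokens[(cursor + 1):length(tokens)])
  relation_instance(new_tokens, new_ents, instance$label, instance$id)
}

# Seeded RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- f(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample = with_state(base::sample),
       sample_int = with_state(base::sample.int),
       rbinom = with_state(stats::rbinom))
}
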