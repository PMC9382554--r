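diag_mass <- function(M) sum(diag(M)) / sum(M)

#' Attention matrices of one instance at three model stages
#'
#' Recovers the three token-by-token weight matrices the heat-map case study
#' compares: `A`, scaled dot-product attention computed directly from the
#' word embeddings (bypassing the encoder, so no syntactic structure is
#' fused); `B`, the model's multi-head attention over the encoder output
#' (averaged over heads); and `C`, the Gaussian-kernel equalization of `B`.
#' Each matrix is row-stochastic.
#'
#' @param model a fitted `"relgcn"` model.
#' @param instance a [relation_instance] with at least 2 tokens.
#' @return list with matrices `A`, `B`, `C`, their diagonal-mass fractions
#'   `diag_mass` (share of total weight on the diagonal; lower means more
#'   nonlocal attention), and the token vector.
#' @export
attention_matrices <- function(model, instance) {
  n <- length(instance$tokens)
  if (n < 2) stop("need at least 2 tokens for attention maps", call. = FALSE)
  if (is.null(model$params$proc))
    stop("feature capture is ablated: no attention layer to inspect",
         call. = FALSE)
  if (model$config$mask_entities) instance <- mask_entities(instance)
  X <- embed_tokens(model$vocab, instance$tokens)
  # A: plain scaled dot-product attention on raw embeddings, no projections
  LA <- tcrossprod(X) / sqrt(ncol(X))
  A <- t(apply(LA, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  enc <- onlstm_encode(X, model$params$enc, model$params$enc_bw)
  heads <- lapply(model$params$proc$attn, function(p)
    attn_head_forward(enc$h, p$Wq, p$Wk)$S)
  B <- Reduce(`+`, heads) / length(heads)
  C <- gaussian_prune(B, model$kernel)
  list(A = A, B = B, C = C,
       diag_mass = c(A = diag_mass(A), B = diag_mass(B), C = diag_mass(C)),
       tokens = instance$tokens)
}

#' Export attention heat maps for one instance
#'
#' Writes the three matrices of [attention_matrices] as full-precision
#' tab-separated text (`A.tsv`, `B.tsv`, `C.tsv`, readable back bit-exactly
#' with [read_matrix]), renders PNG heat maps (`A.png`, ...), and records the
#' diagonal-mass fractions in `diag_mass.tsv`.
#'
#' @param model a fitted `"relgcn"` model.
#' @param instance a [relation_instance] with at least 2 tokens.
#' @param out_dir output directory (created if missing).
#' @param png render PNG heat maps as well as the text matrices.
#' @return (invisibly) the [attention_matrices] list, with `files` attached.
#' @export
export_heatmaps <- function(model, instance, out_dir, png = TRUE) {
  am <- attention_matrices(model, instance)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("A", "B", "C")) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_matrix(am[[nm]], f)
    files <- c(files, f)
    if (png) {
      fp <- file.path(out_dir, paste0(nm, ".png"))
      grDevices::png(fp, width = 640, height = 640)
      n <- nrow(am[[nm]])
      graphics::image(seq_len(n), seq_len(n),
                      t(am[[nm]])[, n:1, drop = FALSE],
                      col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      axes = FALSE, xlab = "", ylab = "",
                      main = paste("attention matrix", nm))
      graphics::axis(1, at = seq_len(n), labels = am$tokens, las = 2,
                     cex.axis = 0.7)
      graphics::axis(2, at = seq_len(n), labels = rev(am$tokens), las = 2,
                     cex.axis = 0.7)
      grDevices::dev.off()
      files <- c(files, fp)
    }
  }
  dm <- file.path(out_dir, "diag_mass.tsv")
  utils::write.table(data.frame(matrix_name = names(am$diag_mass),
                                diag_mass = unname(am$diag_mass)),
                     dm, sep = "\t", row.names = FALSE, quote = FALSE)
  attr(am, "files") <- c(files, dm)
  invisible(am)
}

#' Write / read a numeric matrix as full-precision text
#'
#' Hexadecimal float formatting makes the round-trip bit-exact.
#'
#' @param M numeric matrix.
#' @param path file path.
#' @return `read_matrix` returns the matrix.
#' @export
write_matrix <- function(M, path) {
  lines <- apply(M, 1, function(r) paste(sprintf("%a", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  do.call(rbind, lapply(rows, function(r) strtoi_hexfloat(r)))
}

strtoi_hexfloat <- function(x) {
  # R's as.numeric parses C99 hex floats ("0x1.8p-1") natively
  as.numeric(x)
}

#' Summarize the equalization effect over a corpus
#'
#' For each instance, compares the diagonal mass of the multi-head attention
#' matrix `B` with its Gaussian-equalized counterpart `C` (see
#' [attention_matrices]). An instance counts as "sharp" when `B` concentrates
#' more weight on the diagonal than the uniform matrix would (`1/n`), scaled
#' by `sharp_factor`; only then is there local over-weighting for the kernel
#' to redistribute. The equalization is working as intended when the diagonal
#' mass drops (weight moves to nonlocal interactions) on sharp instances.
#'
#' @param model a fitted `"relgcn"` model.
#' @param corpus list of [relation_instance] objects.
#' @param sharp_factor sharpness threshold: `diag_mass(B) > sharp_factor / n`.
#' @return data frame with per-instance `n`, `diag_A`, `diag_B`, `diag_C`,
#'   `sharp`, and `reduced` (`diag_C <= diag_B`).
#' @export
attention_diagnostics <- function(model, corpus, sharp_factor = 1.2) {
  rows <- lapply(corpus, function(inst) {
    am <- attention_matrices(model, inst)
    n <- length(inst$tokens)
    data.frame(id = inst$id, n = n,
               diag_A = am$diag_mass[["A"]],
               diag_B = am$diag_mass[["B"]],
               diag_C = am$diag_mass[["C"]],
               sharp = am$diag_mass[["B"]] > sharp_factor / n,
               reduced = am$diag_mass[["C"]] <= am$diag_mass[["B"]])
  })
  do.call(rbind, rows)
}
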