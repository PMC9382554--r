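#' Pool token features into a fixed vector
#'
#' Element-wise max (default) or mean over the rows of a feature matrix,
#' restricted to an entity span when one is given, and to unmasked positions
#' otherwise. Spans are 0-based half-open over tokens.
#'
#' @param features n x D matrix.
#' @param span optional integer pair `(start, end)`, 0-based half-open.
#' @param mask optional logical valid-token vector (used when `span` absent).
#' @param type `"max"` or `"mean"`.
#' @return length-D vector.
#' @examples
#' pool(rbind(c(1, 0), c(0, 2), c(-1, -1)), span = c(0, 2))  # c(1, 2)
#' @export
pool <- function(features, span = NULL, mask = NULL, type = c("max", "mean")) {
  type <- match.arg(type)
  pool_forward(features, span, mask, type)$v
}

pool_forward <- function(features, span = NULL, mask = NULL, type = "max") {
  n <- nrow(features)
  if (!is.null(span)) {
    if (span[1] < 0 || span[2] > n || span[1] >= span[2])
      stop("invalid span [", span[1], ",", span[2], ") for ", n, " tokens",
           call. = FALSE)
    rows <- (span[1] + 1):span[2]
  } else {
    rows <- if (is.null(mask)) seq_len(n) else which(mask)
    if (!length(rows)) stop("no valid positions to pool", call. = FALSE)
  }
  sub <- features[rows, , drop = FALSE]
  if (type == "max") {
    arg <- max.col(t(sub), ties.method = "first")   # row of max per column
    v <- sub[cbind(arg, seq_len(ncol(sub)))]
    list(v = v, rows = rows, arg = arg, type = type)
  } else {
    list(v = colMeans(sub), rows = rows, type = type)
  }
}

pool_backward <- function(cache, dv, n, D) {
  dF <- matrix(0, n, D)
  if (cache$type == "max") {
    dF[cbind(cache$rows[cache$arg], seq_len(D))] <- dv
  } else {
    dF[cache$rows, ] <- matrix(dv / length(cache$rows), length(cache$rows),
                               D, byrow = TRUE)
  }
  dF
}

#' Initialize classifier parameters
#'
#' One hidden ReLU layer of width `hidden` over the concatenated pooled
#' vectors, followed by a linear projection to the label logits; the final
#' linear + softmax realizes the logistic-regression output layer.
#'
#' @param input_dim length of the concatenated pooled vector.
#' @param hidden hidden width (conventionally the processor dimension).
#' @param n_labels number of output classes.
#' @param seed integer seed.
#' @return list of weight matrices/biases, class `"classifier_params"`.
#' @export
classifier_params <- function(input_dim, hidden, n_labels, seed = 1L) {
  rng <- local_rng(seed)
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(rng$runif(nr * nc, -r, r), nr, nc)
  }
  structure(list(W1 = glorot(input_dim, hidden), b1 = numeric(hidden),
                 W2 = glorot(hidden, n_labels), b2 = numeric(n_labels)),
            class = "classifier_params")
}

#' Classify pooled sentence and entity representations
#'
#' Concatenates the pooled vectors in fixed order (sentence, subject, object,
#' and optionally third entity), applies the feedforward network, and returns
#' softmax probabilities over the labels.
#'
#' @param inputs list with `H_sent`, `H_s`, `H_o`, optionally `H_third`
#'   (equal-length numeric vectors).
#' @param params a [classifier_params] object.
#' @return numeric probability vector (non-negative, sums to 1).
#' @export
classify <- function(inputs, params) {
  classifier_forward(inputs, params)$p
}

classifier_forward <- function(inputs, params) {
  v <- c(inputs$H_sent, inputs$H_s, inputs$H_o, inputs$H_third)
  if (length(v) != nrow(params$W1))
    stop("classifier input length ", length(v), " != expected ",
         nrow(params$W1), call. = FALSE)
  z1 <- drop(v %*% params$W1) + params$b1
  a1 <- pmax(z1, 0)
  logits <- drop(a1 %*% params$W2) + params$b2
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  list(p = p, v = v, z1 = z1, a1 = a1, logits = logits)
}

# dlogits is typically p - onehot(gold) for cross-entropy
classifier_backward <- function(cache, dlogits, params) {
  dW2 <- tcrossprod(cache$a1, dlogits)
  db2 <- dlogits
  da1 <- drop(params$W2 %*% dlogits)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- tcrossprod(cache$v, dz1)
  db1 <- dz1
  dv <- drop(params$W1 %*% dz1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dv = dv)
}
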