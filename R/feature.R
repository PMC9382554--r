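#' Multi-head attention adjacency matrices
#'
#' Converts encoded token features into fully connected, row-stochastic token
#' graphs, one per head: `S^k = row-softmax((h W^Q)(h W^K)' / sqrt(d_head))`.
#' Each row is a probability distribution over the (unmasked) tokens; the
#' matrices act as soft dependency graphs for the GCN.
#'
#' @param h n x D matrix of encoder hidden states.
#' @param Wq,Wk per-head projection matrices (`D x d_head`), or lists of them
#'   (one per head).
#' @param mask optional logical vector of valid tokens; masked positions get
#'   zero attention, and a fully masked query row falls back to the uniform
#'   distribution over valid tokens.
#' @return a list of n x n row-stochastic matrices, one per head (a single
#'   matrix input returns a single matrix).
#' @export
attention_adjacency <- function(h, Wq, Wk, mask = NULL) {
  single <- !is.list(Wq)
  if (single) { Wq <- list(Wq); Wk <- list(Wk) }
  out <- lapply(seq_along(Wq), function(k)
    attn_head_forward(h, Wq[[k]], Wk[[k]], mask)$S)
  if (single) out[[1]] else out
}

attn_head_forward <- function(h, Wq, Wk, mask = NULL) {
  n <- nrow(h)
  if (is.null(n) || n < 1) stop("need at least one token", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n)
  dh <- ncol(Wq)
  Q <- h %*% Wq
  K <- h %*% Wk
  L <- tcrossprod(Q, K) / sqrt(dh)
  L[, !mask] <- -Inf
  S <- matrix(0, n, n)
  for (r in seq_len(n)) {
    row <- L[r, ]
    mx <- max(row[mask])
    e <- ifelse(is.finite(row), exp(row - mx), 0)
    s <- sum(e)
    S[r, ] <- if (s > 0) e / s else mask / sum(mask)
  }
  list(S = S, Q = Q, K = K, mask = mask, dh = dh)
}

attn_head_backward <- function(cache, dS, h, Wq, Wk) {
  S <- cache$S; mask <- cache$mask; dh_dim <- cache$dh
  n <- nrow(S)
  dL <- S * (dS - rowSums(dS * S))     # row-wise softmax backward
  dL[, !mask] <- 0
  dQ <- dL %*% cache$K / sqrt(dh_dim)
  dK <- crossprod(dL, cache$Q) / sqrt(dh_dim)
  list(dh = dQ %*% t(Wq) + dK %*% t(Wk),
       dWq = crossprod(h, dQ),
       dWk = crossprod(h, dK))
}

#' Specify a two-dimensional Gaussian kernel
#'
#' Parameters of the discrete 2-D Gaussian used to equalize attention
#' matrices: `g(x, y) = a * exp(-((x - xo)^2 / (2 sx^2) +
#' (y - yo)^2 / (2 sy^2)))`, evaluated on an odd `size x size` integer grid
#' centered at `(xo, yo)`. With `normalize = TRUE` the discrete entries are
#' divided by their sum (so the amplitude cancels and convolution preserves
#' total mass).
#'
#' @param size odd window side length (>= 1).
#' @param amplitude peak value `a`.
#' @param center numeric pair `(xo, yo)`.
#' @param sigma numeric pair `(sx, sy)`, both positive.
#' @param normalize divide by the discrete sum.
#' @return an object of class `"gaussian_kernel_spec"`.
#' @export
gaussian_kernel_spec <- function(size = 3L, amplitude = 1, center = c(0, 0),
                                 sigma = c(1, 1), normalize = TRUE) {
  size <- as.integer(size)
  if (size < 1 || size %% 2 == 0)
    stop("kernel size must be an odd integer >= 1", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  structure(list(size = size, amplitude = amplitude, center = center,
                 sigma = sigma, normalize = isTRUE(normalize)),
            class = "gaussian_kernel_spec")
}

#' Build the discrete Gaussian kernel matrix
#'
#' @param spec a [gaussian_kernel_spec].
#' @return `size x size` numeric matrix; entries sum to 1 when normalized.
#' @examples
#' build_gaussian_kernel(gaussian_kernel_spec(size = 3))
#' @export
build_gaussian_kernel <- function(spec) {
  stopifnot(inherits(spec, "gaussian_kernel_spec"))
  r <- (spec$size - 1L) / 2L
  gx <- spec$center[1] + (-r:r)
  gy <- spec$center[2] + (-r:r)
  kx <- exp(-(gx - spec$center[1])^2 / (2 * spec$sigma[1]^2))
  ky <- exp(-(gy - spec$center[2])^2 / (2 * spec$sigma[2]^2))
  ker <- spec$amplitude * outer(kx, ky)
  if (spec$normalize) ker <- ker / sum(ker)
  ker
}

crop_kernel <- function(ker, n) {
  # attention map smaller than the kernel: trim outer rings, renormalize
  while (nrow(ker) > max(1L, 2L * n - 1L) || nrow(ker) > n) {
    ker <- ker[2:(nrow(ker) - 1), 2:(ncol(ker) - 1), drop = FALSE]
  }
  ker / sum(ker)
}

#' Equalize an attention matrix with a Gaussian kernel
#'
#' The "pruning" step that balances local and nonlocal interaction weights:
#' the n x n attention map is convolved with a normalized 2-D Gaussian kernel
#' under replicate padding (each output entry is a convex average of its
#' receptive field), then rows are renormalized to restore row-stochasticity.
#' Sharp attention peaks are flattened, spreading weight onto nonlocal
#' neighbors, which is exactly the image-equalization analogy the kernel is
#' borrowed from.
#'
#' @param raw n x n non-negative matrix (typically row-stochastic attention).
#' @param kernel normalized non-negative kernel matrix (odd side length), or a
#'   [gaussian_kernel_spec]. Kernels larger than the matrix are cropped to fit
#'   and renormalized.
#' @return n x n row-stochastic matrix.
#' @export
gaussian_prune <- function(raw, kernel = gaussian_kernel_spec()) {
  fw <- gaussian_prune_forward(raw, kernel)
  fw$A
}

gaussian_prune_forward <- function(raw, kernel) {
  if (inherits(kernel, "gaussian_kernel_spec"))
    kernel <- build_gaussian_kernel(kernel)
  if (any(kernel < 0)) stop("kernel must be non-negative", call. = FALSE)
  kernel <- kernel / sum(kernel)
  n <- nrow(raw)
  if (nrow(kernel) > n) kernel <- crop_kernel(kernel, n)
  r <- (nrow(kernel) - 1L) / 2L
  P <- matrix(0, n, n)
  idx <- lapply(-r:r, function(u) pmin(pmax(seq_len(n) + u, 1L), n))
  for (u in -r:r) for (v in -r:r) {
    w <- kernel[u + r + 1L, v + r + 1L]
    if (w != 0) P <- P + w * raw[idx[[u + r + 1L]], idx[[v + r + 1L]]]
  }
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  list(A = P / rs, P = P, rs = rs, kernel = kernel, idx = idx, r = r, n = n)
}

gaussian_prune_backward <- function(cache, dA) {
  n <- cache$n; r <- cache$r; kernel <- cache$kernel
  # renormalization backward: A_ij = P_ij / s_i
  dP <- (dA - rowSums(dA * cache$A)) / cache$rs
  dRaw <- matrix(0, n, n)
  sel <- lapply(cache$idx, function(ri) {
    M <- matrix(0, n, n); M[cbind(seq_len(n), ri)] <- 1; M
  })
  for (u in -r:r) for (v in -r:r) {
    w <- kernel[u + r + 1L, v + r + 1L]
    if (w != 0)
      dRaw <- dRaw + w * crossprod(sel[[u + r + 1L]], dP %*% sel[[v + r + 1L]])
  }
  dRaw
}

activation_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
         tanh = list(f = tanh, df = function(z, a) 1 - a^2),
         identity = list(f = identity, df = function(z, a) 1),
         stop("unknown activation: ", name, call. = FALSE))
}

#' One graph-convolution layer
#'
#' Layer-wise propagation over a token graph with self-loops:
#' `H^(l+1) = act(D^-1 (A + I) H^(l) W)`, where `D` is the diagonal row-sum
#' (degree) matrix of `A + I`. Row normalization (rather than the symmetric
#' form) is used because attention adjacencies are asymmetric. The self-loop
#' guarantees every degree is at least 1.
#'
#' @param H n x D input node features.
#' @param A n x n non-negative adjacency (no self-loops required).
#' @param W D x D_out weight matrix.
#' @param activation `"relu"`, `"tanh"`, or `"identity"`.
#' @param mask optional logical vector; masked rows are zeroed in the output.
#' @return n x D_out matrix.
#' @export
gcn_layer <- function(H, A, W, activation = "relu", mask = NULL) {
  gcn_layer_forward(H, A, W, activation, mask)$out
}

gcn_layer_forward <- function(H, A, W, activation = "relu", mask = NULL) {
  if (any(A < 0)) stop("adjacency must be non-negative", call. = FALSE)
  n <- nrow(A)
  At <- A + diag(n)
  deg <- rowSums(At)
  M <- At / deg
  B <- H %*% W
  Z <- M %*% B
  act <- activation_fun(activation)
  out <- act$f(Z)
  if (!is.null(mask)) out[!mask, ] <- 0
  list(out = out, M = M, Z = Z, deg = deg, H = H, W = W,
       activation = activation, mask = mask)
}

gcn_layer_backward <- function(cache, dOut) {
  act <- activation_fun(cache$activation)
  if (!is.null(cache$mask)) dOut[!cache$mask, ] <- 0
  dZ <- dOut * act$df(cache$Z, act$f(cache$Z))
  B <- cache$H %*% cache$W
  dM <- tcrossprod(dZ, B)
  dB <- crossprod(cache$M, dZ)
  dH <- tcrossprod(dB, cache$W)      # dB %*% t(W)
  dW <- crossprod(cache$H, dB)
  # M = At / deg (row-wise); dAt_ij = (dM_ij - sum_k dM_ik M_ik) / deg_i
  dAt <- (dM - rowSums(dM * cache$M)) / cache$deg
  list(dH = dH, dW = dW, dA = dAt)   # dA == dAt (self-loop is constant)
}

#' Run the full feature processor
#'
#' For each attention head: build the attention adjacency from the encoder
#' output, optionally equalize it with the Gaussian kernel, and propagate the
#' encoder features through `L` GCN layers over that graph. Head outputs are
#' concatenated and linearly mixed to the processor output dimension.
#'
#' Ablation switches mirror the model's ablation study: `use_pruning = FALSE`
#' skips the kernel equalization; `use_feature_capture = FALSE` bypasses the
#' attention + GCN stack entirely (the processor becomes the identity on `h`).
#' Setting `use_feature_capture = FALSE` together with `use_pruning = TRUE` is
#' contradictory (there is no attention graph to prune) and raises an error.
#'
#' @param h n x D encoder output.
#' @param params list with `attn` (per-head `Wq`, `Wk`), `gcn` (per-head list
#'   of layer weights), `mix` (`W`, `b`).
#' @param kernel kernel matrix or [gaussian_kernel_spec].
#' @param use_pruning,use_feature_capture ablation switches.
#' @param activation GCN activation name.
#' @param mask optional logical valid-token vector.
#' @param residual add a shortcut connection from `h` to the mixed output
#'   (requires D' = D); the usual stabilizer for stacked graph layers in
#'   this model family.
#' @return n x D' matrix of node features.
#' @export
feature_process <- function(h, params, kernel = gaussian_kernel_spec(),
                            use_pruning = TRUE, use_feature_capture = TRUE,
                            activation = "relu", mask = NULL,
                            residual = FALSE) {
  feature_process_forward(h, params, kernel, use_pruning,
                          use_feature_capture, activation, mask, residual)$out
}

feature_process_forward <- function(h, params, kernel, use_pruning,
                                    use_feature_capture, activation,
                                    mask = NULL, residual = FALSE) {
  if (!use_feature_capture && use_pruning)
    stop("contradictory ablation flags: pruning requires the attention graph",
         call. = FALSE)
  if (!use_feature_capture)
    return(list(out = h, identity = TRUE))
  K <- length(params$attn)
  heads <- vector("list", K)
  outs <- vector("list", K)
  for (k in seq_len(K)) {
    at <- attn_head_forward(h, params$attn[[k]]$Wq, params$attn[[k]]$Wk, mask)
    pr <- if (use_pruning) gaussian_prune_forward(at$S, kernel) else NULL
    A <- if (use_pruning) pr$A else at$S
    layers <- vector("list", length(params$gcn[[k]]))
    Hl <- h
    for (l in seq_along(params$gcn[[k]])) {
      layers[[l]] <- gcn_layer_forward(Hl, A, params$gcn[[k]][[l]],
                                       activation, mask)
      Hl <- layers[[l]]$out
    }
    heads[[k]] <- list(at = at, pr = pr, layers = layers)
    outs[[k]] <- Hl
  }
  concat <- do.call(cbind, outs)
  out <- concat %*% params$mix$W +
    matrix(params$mix$b, nrow(h), length(params$mix$b), byrow = TRUE)
  if (residual) {
    if (ncol(out) != ncol(h))
      stop("residual shortcut requires matching dimensions (D' = D)",
           call. = FALSE)
    out <- out + h
  }
  list(out = out, heads = heads, concat = concat, identity = FALSE,
       use_pruning = use_pruning, residual = residual, h = h)
}

feature_process_backward <- function(cache, dOut, params) {
  if (isTRUE(cache$identity))
    return(list(dh = dOut, grads = NULL))
  K <- length(params$attn)
  dConcat <- tcrossprod(dOut, params$mix$W)      # dOut %*% t(W)
  gmix <- list(W = crossprod(cache$concat, dOut), b = colSums(dOut))
  dh <- matrix(0, nrow(cache$h), ncol(cache$h))
  gattn <- vector("list", K)
  ggcn <- vector("list", K)
  Dg <- ncol(cache$concat) / K
  for (k in seq_len(K)) {
    hd <- cache$heads[[k]]
    Llen <- length(hd$layers)
    dHl <- dConcat[, (k - 1) * Dg + seq_len(Dg), drop = FALSE]
    dA <- matrix(0, nrow(dh), nrow(dh))
    gW <- vector("list", Llen)
    for (l in Llen:1) {
      bk <- gcn_layer_backward(hd$layers[[l]], dHl)
      gW[[l]] <- bk$dW
      dA <- dA + bk$dA
      dHl <- bk$dH
    }
    dh <- dh + dHl                      # H^(0) = h
    dS <- if (cache$use_pruning) gaussian_prune_backward(hd$pr, dA) else dA
    ab <- attn_head_backward(hd$at, dS, cache$h,
                             params$attn[[k]]$Wq, params$attn[[k]]$Wk)
    dh <- dh + ab$dh
    gattn[[k]] <- list(Wq = ab$dWq, Wk = ab$dWk)
    ggcn[[k]] <- gW
  }
  if (isTRUE(cache$residual)) dh <- dh + dOut
  list(dh = dh, grads = list(attn = gattn, gcn = ggcn, mix = gmix))
}
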