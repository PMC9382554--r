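#' Cumulative softmax (cumax)
#'
#' The activation behind ordered-neuron master gates: the cumulative sum of a
#' softmax. The output is non-decreasing, lies in (0, 1], and its last entry
#' is exactly 1 (up to float rounding). Interpreted as a soft split point: the
#' softmax predicts the "layer order" of neurons and the cumulative sum turns
#' it into a monotone gate separating low-order (frequently updated) from
#' high-order (long-lived) neurons.
#'
#' @param logits numeric vector, finite.
#' @return numeric vector of the same length.
#' @examples
#' cumax(c(0, 0, 0))   # 1/3, 2/3, 1
#' @export
cumax <- function(logits) {
  if (!length(logits)) stop("cumax needs at least one logit", call. = FALSE)
  if (!all(is.finite(logits)))
    stop("cumax requires finite logits", call. = FALSE)
  e <- exp(logits - max(logits))
  cumsum(e / sum(e))
}

# gradient of sum(dy * cumax(l)) w.r.t. l, given softmax probs p
cumax_backward <- function(dy, p) {
  dp <- rev(cumsum(rev(dy)))
  p * (dp - sum(dp * p))
}

#' Initialize ordered-neuron LSTM parameters
#'
#' Standard LSTM gate projections (forget, input, output, candidate) plus the
#' two master-gate projections that predict the chunk-level layer order. The
#' hidden dimension `d` is split into `d / chunk_size` chunks; master gates
#' are computed at chunk granularity and broadcast within chunks, keeping the
#' layer-order softmax sharp even at large `d`.
#'
#' Initialization is uniform Glorot; gate biases are zero except the forget
#' bias (+1, the usual recurrent-network convention).
#'
#' @param input_dim embedding dimension fed to the cell.
#' @param hidden_dim hidden state size `d`.
#' @param chunk_size master-gate chunk width; must divide `hidden_dim`.
#' @param seed integer seed for the initialization draw.
#' @return an object of class `"onlstm_params"`.
#' @export
onlstm_params <- function(input_dim, hidden_dim, chunk_size = 10L, seed = 1L) {
  d <- as.integer(hidden_dim); e <- as.integer(input_dim)
  cs <- as.integer(chunk_size)
  if (d %% cs != 0)
    stop("chunk_size (", cs, ") must divide hidden_dim (", d, ")",
         call. = FALSE)
  m <- d %/% cs
  rng <- local_rng(seed)
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(rng$runif(nr * nc, -r, r), nr, nc)
  }
  b <- numeric(4 * d)
  b[seq_len(d)] <- 1            # forget-gate bias
  structure(list(
    W = glorot(e, 4L * d), U = glorot(d, 4L * d), b = b,
    Wmf = glorot(e, m), Umf = glorot(d, m), bmf = numeric(m),
    Wmi = glorot(e, m), Umi = glorot(d, m), bmi = numeric(m),
    input_dim = e, hidden_dim = d, chunk_size = cs, n_chunks = m),
    class = "onlstm_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One ordered-neuron LSTM step
#'
#' Computes the standard sigmoid/tanh gates, the chunk-level master forget
#' gate (a cumax, non-decreasing 0 to 1 along the chunk axis) and master input
#' gate (one minus a cumax, non-increasing 1 to 0), their overlap
#' `omega = mf * mi`, and the segmented cell update
#' `c_t = omega*(f*c_prev + i*g) + (mf - omega)*c_prev + (mi - omega)*g`,
#' where `g` is the tanh candidate. With both master gates pinned to 1 the
#' update collapses to the plain LSTM `c_t = f*c_prev + i*g`.
#'
#' @param x input vector (length `input_dim`).
#' @param h_prev,c_prev previous hidden and cell state (length `hidden_dim`).
#' @param params an [onlstm_params] object.
#' @param pin_master if `TRUE`, force both master gates to all-ones (plain
#'   LSTM limit; used for oracle checks).
#' @return list with `h`, `c`, `master_forget`, `master_input`, `overlap`.
#' @export
onlstm_cell <- function(x, h_prev, c_prev, params, pin_master = FALSE) {
  e <- params$input_dim; d <- params$hidden_dim
  if (length(x) != e) stop("input length ", length(x), " != input_dim ", e,
                           call. = FALSE)
  if (length(h_prev) != d || length(c_prev) != d)
    stop("state length must equal hidden_dim ", d, call. = FALSE)
  st <- onlstm_step(x, h_prev, c_prev, params,
                    xW = NULL, xWmf = NULL, xWmi = NULL, pin_master)
  st[c("h", "c", "master_forget", "master_input", "overlap")]
}

# core step; xW/xWmf/xWmi allow the per-sequence precomputation in encode()
onlstm_step <- function(x, h_prev, c_prev, params, xW, xWmf, xWmi,
                        pin_master = FALSE) {
  d <- params$hidden_dim; cs <- params$chunk_size; m <- params$n_chunks
  if (is.null(xW)) {
    xW <- drop(x %*% params$W)
    xWmf <- drop(x %*% params$Wmf)
    xWmi <- drop(x %*% params$Wmi)
  }
  z <- xW + drop(h_prev %*% params$U) + params$b
  f <- sigmoid(z[seq_len(d)])
  i <- sigmoid(z[d + seq_len(d)])
  o <- sigmoid(z[2L * d + seq_len(d)])
  g <- tanh(z[3L * d + seq_len(d)])
  if (pin_master) {
    pf <- pi_ <- NULL
    mf <- mi <- rep(1, d)
  } else {
    lf <- xWmf + drop(h_prev %*% params$Umf) + params$bmf
    li <- xWmi + drop(h_prev %*% params$Umi) + params$bmi
    ef <- exp(lf - max(lf)); pf <- ef / sum(ef)
    ei <- exp(li - max(li)); pi_ <- ei / sum(ei)
    mf <- rep(cumsum(pf), each = cs)
    mi <- rep(1 - cumsum(pi_), each = cs)
  }
  om <- mf * mi
  Fg <- om * f + (mf - om)
  Ig <- om * i + (mi - om)
  cc <- Fg * c_prev + Ig * g
  tc <- tanh(cc)
  list(h = o * tc, c = cc, master_forget = mf, master_input = mi,
       overlap = om, f = f, i = i, o = o, g = g, pf = pf, pi_ = pi_,
       Fg = Fg, Ig = Ig, tc = tc)
}

#' Encode a token sequence with the ordered-neuron LSTM
#'
#' Left-to-right recurrence of [onlstm_cell] over the rows of `X`, starting
#' from zero-filled states. The optional bidirectional variant runs a second,
#' independently parameterized pass over the reversed sequence and
#' concatenates the two hidden states (output dimension `2d`).
#'
#' @param X n x input_dim matrix of token embeddings (n >= 1).
#' @param params an [onlstm_params] for the forward pass.
#' @param params_bw optional [onlstm_params] for a backward pass
#'   (bidirectional encoding).
#' @param pin_master pin master gates to 1 (plain-LSTM limit).
#' @return an object of class `"encoder_state"` with fields `h` (n x d or
#'   n x 2d), `c`, `master_forget`, `master_input`, `overlap` (each n x d,
#'   forward-pass gates), and an internal cache for backpropagation.
#' @export
onlstm_encode <- function(X, params, params_bw = NULL, pin_master = FALSE) {
  if (!is.matrix(X) || nrow(X) < 1)
    stop("X must be a matrix with at least one row", call. = FALSE)
  if (ncol(X) != params$input_dim)
    stop("ncol(X) = ", ncol(X), " != input_dim ", params$input_dim,
         call. = FALSE)
  fwd <- onlstm_pass(X, params, pin_master)
  if (is.null(params_bw)) {
    st <- fwd
    h <- fwd$h
  } else {
    bwd <- onlstm_pass(X[nrow(X):1, , drop = FALSE], params_bw, pin_master)
    h <- cbind(fwd$h, bwd$h[nrow(X):1, , drop = FALSE])
    st <- fwd
    st$bw <- bwd
  }
  structure(list(h = h, c = fwd$cmat,
                 master_forget = fwd$master_forget,
                 master_input = fwd$master_input,
                 overlap = fwd$overlap,
                 cache = st, X = X, pin_master = pin_master),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  cat("<encoder_state> ", nrow(x$h), " tokens, hidden dim ", ncol(x$h),
      if (!is.null(x$cache$bw)) " (bidirectional)", "\n", sep = "")
  invisible(x)
}

onlstm_pass <- function(X, params, pin_master = FALSE) {
  n <- nrow(X); d <- params$hidden_dim; m <- params$n_chunks
  XW <- X %*% params$W
  XWmf <- X %*% params$Wmf
  XWmi <- X %*% params$Wmi
  h <- matrix(0, n, d); cmat <- matrix(0, n, d)
  mfm <- matrix(0, n, d); mim <- matrix(0, n, d); omm <- matrix(0, n, d)
  steps <- vector("list", n)
  h_prev <- numeric(d); c_prev <- numeric(d)
  for (t in seq_len(n)) {
    st <- onlstm_step(NULL, h_prev, c_prev, params,
                      XW[t, ], XWmf[t, ], XWmi[t, ], pin_master)
    h[t, ] <- st$h; cmat[t, ] <- st$c
    mfm[t, ] <- st$master_forget; mim[t, ] <- st$master_input
    omm[t, ] <- st$overlap
    steps[[t]] <- st
    h_prev <- st$h; c_prev <- st$c
  }
  list(h = h, cmat = cmat, master_forget = mfm, master_input = mim,
       overlap = omm, steps = steps, X = X)
}

# Backprop through one directional pass. dH: n x d gradient wrt hidden states.
# Returns dX (n x e) and a grads list shaped like the params.
onlstm_pass_backward <- function(pass, dH, params) {
  X <- pass$X; steps <- pass$steps
  n <- nrow(X); d <- params$hidden_dim
  cs <- params$chunk_size; m <- params$n_chunks
  dZ <- matrix(0, n, 4L * d)
  dLf <- matrix(0, n, m); dLi <- matrix(0, n, m)
  dh_next <- numeric(d); dc_next <- numeric(d)
  pin <- is.null(steps[[1]]$pf)
  for (t in n:1) {
    st <- steps[[t]]
    c_prev <- if (t > 1) steps[[t - 1]]$c else numeric(d)
    dh <- dH[t, ] + dh_next
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    dF <- dc * c_prev
    dI <- dc * st$g
    dc_next <- dc * st$Fg
    dg <- dc * st$Ig
    df <- dF * st$overlap
    di <- dI * st$overlap
    dz <- c(df * st$f * (1 - st$f),
            di * st$i * (1 - st$i),
            do * st$o * (1 - st$o),
            dg * (1 - st$g^2))
    dZ[t, ] <- dz
    dh_prev <- drop(params$U %*% dz)
    if (!pin) {
      dom <- dF * (st$f - 1) + dI * (st$i - 1)
      dmf <- dF + dom * st$master_input
      dmi <- dI + dom * st$master_forget
      dmf_c <- colSums(matrix(dmf, nrow = cs))
      dmi_c <- colSums(matrix(dmi, nrow = cs))
      dlf <- cumax_backward(dmf_c, st$pf)
      dli <- cumax_backward(-dmi_c, st$pi_)   # mi = 1 - cumax
      dLf[t, ] <- dlf; dLi[t, ] <- dli
      dh_prev <- dh_prev + drop(params$Umf %*% dlf) + drop(params$Umi %*% dli)
    }
    dh_next <- dh_prev
  }
  Hprev <- rbind(numeric(d), pass$h[-n, , drop = FALSE])
  grads <- list(
    W = crossprod(X, dZ), U = crossprod(Hprev, dZ), b = colSums(dZ),
    Wmf = crossprod(X, dLf), Umf = crossprod(Hprev, dLf), bmf = colSums(dLf),
    Wmi = crossprod(X, dLi), Umi = crossprod(Hprev, dLi), bmi = colSums(dLi))
  dX <- dZ %*% t(params$W) + dLf %*% t(params$Wmf) + dLi %*% t(params$Wmi)
  list(dX = dX, grads = grads)
}

# Backprop through onlstm_encode. dH matches state$h (n x d or n x 2d).
onlstm_encode_backward <- function(state, dH, params, params_bw = NULL) {
  n <- nrow(state$X); d <- params$hidden_dim
  fwd <- onlstm_pass_backward(state$cache, dH[, seq_len(d), drop = FALSE],
                              params)
  if (is.null(params_bw)) return(list(dX = fwd$dX, grads = fwd$grads,
                                      grads_bw = NULL))
  dHb <- dH[n:1, d + seq_len(d), drop = FALSE]
  bwd <- onlstm_pass_backward(state$cache$bw, dHb, params_bw)
  list(dX = fwd$dX + bwd$dX[n:1, , drop = FALSE],
       grads = fwd$grads, grads_bw = bwd$grads)
}
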