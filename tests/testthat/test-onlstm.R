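test_that("cumax matches the softmax+cumsum oracle and its contracts", {
  expect_equal(cumax(c(0, 0, 0)), c(1 / 3, 2 / 3, 1))
  expect_equal(cumax(5), 1)
  # hand-computed two-point case
  sm <- exp(c(5, -5)) / sum(exp(c(5, -5)))
  expect_equal(cumax(c(5, -5)), cumsum(sm))
  expect_equal(cumax(c(5, -5))[1], 0.9999546, tolerance = 1e-6)

  set.seed(101)
  for (i in 1:200) {
    m <- sample(1:64, 1)
    l <- stats::rnorm(m, sd = 3)
    y <- cumax(l)
    ref <- cumsum(exp(l - max(l)) / sum(exp(l - max(l))))
    expect_equal(y, ref)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y > 0 & y <= 1 + 1e-12))
    expect_equal(y[m], 1, tolerance = 1e-9)
  }
  expect_error(cumax(c(1, Inf)), "finite")
  expect_error(cumax(numeric(0)), "at least one")
})

test_that("a single cell step honors the segmented update and its zero case", {
  p <- onlstm_params(4, 8, chunk_size = 4, seed = 11)
  # zero input, zero states, zero biases -> candidate 0 -> cell 0 -> h 0
  p0 <- p; p0$b <- numeric(32)
  st <- onlstm_cell(numeric(4), numeric(8), numeric(8), p0)
  expect_equal(st$c, rep(0, 8))
  expect_equal(st$h, rep(0, 8))
  # overlap is the product of the master gates
  x <- stats::rnorm(4); h <- stats::rnorm(8); cc <- stats::rnorm(8)
  st2 <- onlstm_cell(x, h, cc, p)
  expect_equal(st2$overlap, st2$master_forget * st2$master_input)
  expect_error(onlstm_cell(numeric(3), h, cc, p), "input_dim")
})

test_that("master gates are monotone and bounded over random draws", {
  set.seed(202)
  for (i in 1:100) {
    p <- onlstm_params(5, 12, chunk_size = 3, seed = i)
    x <- stats::rnorm(5, sd = 2)
    h <- stats::rnorm(12); cc <- stats::rnorm(12)
    st <- onlstm_cell(x, h, cc, p)
    expect_true(all(st$master_forget >= -1e-12 & st$master_forget <= 1 + 1e-12))
    expect_true(all(st$master_input >= -1e-12 & st$master_input <= 1 + 1e-12))
    expect_true(all(diff(st$master_forget) >= -1e-12))
    expect_true(all(diff(st$master_input) <= 1e-12))
  }
})

test_that("pinning the master gates reproduces an independent plain LSTM", {
  set.seed(303)
  for (i in 1:20) {
    e <- sample(2:6, 1); d <- 2 * sample(2:16, 1); n <- sample(1:10, 1)
    p <- onlstm_params(e, d, chunk_size = 2, seed = 300 + i)
    X <- matrix(stats::rnorm(n * e), n, e)
    enc <- onlstm_encode(X, p, pin_master = TRUE)
    ref <- reference_lstm(X, p$W, p$U, p$b)
    expect_equal(enc$h, ref, tolerance = 1e-6)
  }
})

test_that("encoding is sequential, order-sensitive, and shape-correct", {
  p <- onlstm_params(6, 8, chunk_size = 4, seed = 31)
  set.seed(44)
  X <- matrix(stats::rnorm(5 * 6), 5, 6)
  enc <- onlstm_encode(X, p)
  expect_identical(dim(enc$h), c(5L, 8L))
  expect_identical(dim(enc$master_forget), c(5L, 8L))

  # n = 1 reduces to a single cell step from zero states
  enc1 <- onlstm_encode(X[1, , drop = FALSE], p)
  cell <- onlstm_cell(X[1, ], numeric(8), numeric(8), p)
  expect_equal(drop(enc1$h), cell$h)

  # permuting the tokens changes the encoding
  encp <- onlstm_encode(X[c(2, 1, 3, 5, 4), ], p)
  expect_gt(max(abs(encp$h - enc$h)), 1e-6)

  # bidirectional doubles the output width
  p_bw <- onlstm_params(6, 8, chunk_size = 4, seed = 32)
  encb <- onlstm_encode(X, p, params_bw = p_bw)
  expect_identical(dim(encb$h), c(5L, 16L))
  expect_equal(encb$h[, 1:8], enc$h)

  expect_error(onlstm_encode(matrix(0, 0, 6), p), "at least one row")
})

test_that("analytic encoder gradients match central finite differences", {
  p <- onlstm_params(5, 8, chunk_size = 4, seed = 77)
  set.seed(88)
  X <- matrix(stats::rnorm(4 * 5), 4, 5)
  R <- matrix(stats::rnorm(4 * 8), 4, 8)   # random linear readout
  loss_of <- function(pp) sum(onlstm_encode(X, pp)$h * R)

  enc <- onlstm_encode(X, p)
  bk <- relgcn:::onlstm_encode_backward(enc, R, p)

  theta <- relgcn:::params_flatten(p)
  gvec <- relgcn:::params_flatten(
    relgcn:::params_axpy(relgcn:::grads_scale(p, 0), bk$grads, 1))
  f <- function(th) loss_of(relgcn:::params_unflatten(th, p))
  num <- numeric_grad(f, theta)
  expect_lt(max(abs(num - gvec) / pmax(1e-4, abs(num) + abs(gvec))), 1e-4)

  # input gradient as well
  gX <- matrix(0, 4, 5)
  for (j in seq_along(X)) {
    Xp <- X; Xp[j] <- Xp[j] + 1e-5
    Xm <- X; Xm[j] <- Xm[j] - 1e-5
    gX[j] <- (sum(onlstm_encode(Xp, p)$h * R) -
              sum(onlstm_encode(Xm, p)$h * R)) / 2e-5
  }
  expect_equal(bk$dX, gX, tolerance = 1e-5)
})

test_that("bidirectional encoding backpropagates through both passes", {
  p <- onlstm_params(4, 6, chunk_size = 3, seed = 91)
  p_bw <- onlstm_params(4, 6, chunk_size = 3, seed = 92)
  set.seed(93)
  X <- matrix(stats::rnorm(3 * 4), 3, 4)
  R <- matrix(stats::rnorm(3 * 12), 3, 12)
  enc <- onlstm_encode(X, p, params_bw = p_bw)
  bk <- relgcn:::onlstm_encode_backward(enc, R, p, p_bw)

  loss_of <- function(pf, pb, Xi) sum(onlstm_encode(Xi, pf, params_bw = pb)$h * R)
  for (which in c("fw", "bw")) {
    pp <- if (which == "fw") p else p_bw
    gr <- if (which == "fw") bk$grads else bk$grads_bw
    theta <- relgcn:::params_flatten(pp)
    gvec <- relgcn:::params_flatten(
      relgcn:::params_axpy(relgcn:::grads_scale(pp, 0), gr, 1))
    f <- function(th) {
      pu <- relgcn:::params_unflatten(th, pp)
      if (which == "fw") loss_of(pu, p_bw, X) else loss_of(p, pu, X)
    }
    num <- numeric_grad(f, theta)
    expect_lt(max(abs(num - gvec) / pmax(1e-4, abs(num) + abs(gvec))), 1e-4)
  }
  gX <- matrix(0, 3, 4)
  for (j in seq_along(X)) {
    Xp <- X; Xp[j] <- Xp[j] + 1e-5
    Xm <- X; Xm[j] <- Xm[j] - 1e-5
    gX[j] <- (loss_of(p, p_bw, Xp) - loss_of(p, p_bw, Xm)) / 2e-5
  }
  expect_equal(bk$dX, gX, tolerance = 1e-5)
})
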