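test_that("attention adjacency rows are probability distributions", {
  set.seed(11)
  h <- matrix(stats::rnorm(5 * 8), 5, 8)
  Wq <- list(matrix(stats::rnorm(8 * 4, sd = 0.5), 8, 4),
             matrix(stats::rnorm(8 * 4, sd = 0.5), 8, 4))
  Wk <- list(matrix(stats::rnorm(8 * 4, sd = 0.5), 8, 4),
             matrix(stats::rnorm(8 * 4, sd = 0.5), 8, 4))
  S <- attention_adjacency(h, Wq, Wk)
  expect_length(S, 2)
  for (Sk in S) {
    expect_identical(dim(Sk), c(5L, 5L))
    expect_true(all(Sk >= 0))
    expect_equal(rowSums(Sk), rep(1, 5), tolerance = 1e-6)
  }

  # n = 1: the only token attends to itself
  S1 <- attention_adjacency(h[1, , drop = FALSE], Wq[[1]], Wk[[1]])
  expect_equal(S1, matrix(1, 1, 1))

  # zero projections: uniform rows
  S0 <- attention_adjacency(h, matrix(0, 8, 4), matrix(0, 8, 4))
  expect_equal(S0, matrix(1 / 5, 5, 5))

  # masked positions receive no attention; rows renormalize over valid tokens
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  Sm <- attention_adjacency(h, Wq[[1]], Wk[[1]], mask = mask)
  expect_equal(unname(Sm[, 4:5]), matrix(0, 5, 2))
  expect_equal(rowSums(Sm), rep(1, 5), tolerance = 1e-6)
})

test_that("the discrete Gaussian kernel matches its closed form", {
  expect_equal(build_gaussian_kernel(gaussian_kernel_spec(size = 1)),
               matrix(1, 1, 1))
  expect_equal(build_gaussian_kernel(
    gaussian_kernel_spec(size = 1, amplitude = 3, normalize = FALSE)),
    matrix(3, 1, 1))

  k3 <- build_gaussian_kernel(gaussian_kernel_spec(size = 3))
  center_ref <- 1 / (1 + 4 * exp(-1 / 2) + 4 * exp(-1))
  expect_equal(k3[2, 2], center_ref, tolerance = 1e-10)
  expect_equal(sum(k3), 1)
  expect_equal(k3, t(k3))                     # isotropic sigma -> symmetric

  # large sigma limit: approaches the uniform kernel
  kflat <- build_gaussian_kernel(gaussian_kernel_spec(size = 3,
                                                      sigma = c(100, 100)))
  expect_true(all(abs(kflat - 1 / 9) < 1e-3))

  expect_error(gaussian_kernel_spec(size = 4), "odd")
  expect_error(gaussian_kernel_spec(sigma = c(0, 1)), "positive")
})

test_that("kernel equalization preserves row-stochasticity and local bounds", {
  set.seed(22)
  ker <- build_gaussian_kernel(gaussian_kernel_spec(size = 3))

  # identity (delta) kernel leaves the matrix bit-exactly unchanged
  M <- matrix(stats::runif(36), 6, 6); M <- M / rowSums(M)
  expect_identical(gaussian_prune(M, matrix(1, 1, 1)), M)

  # constant matrix is a fixed point of smoothing
  U <- matrix(1 / 6, 6, 6)
  expect_equal(gaussian_prune(U, ker), U, tolerance = 1e-12)

  for (i in 1:50) {
    n <- sample(3:9, 1)
    A <- matrix(stats::runif(n * n), n, n); A <- A / rowSums(A)
    fw <- relgcn:::gaussian_prune_forward(A, ker)
    # every convolved entry lies within [min, max] of its receptive field
    r <- 1L
    for (ii in seq_len(n)) for (jj in seq_len(n)) {
      ri <- pmin(pmax((ii - r):(ii + r), 1L), n)
      ci <- pmin(pmax((jj - r):(jj + r), 1L), n)
      rf <- A[ri, ci]
      expect_gte(fw$P[ii, jj], min(rf) - 1e-12)
      expect_lte(fw$P[ii, jj], max(rf) + 1e-12)
    }
    expect_equal(rowSums(fw$A), rep(1, n), tolerance = 1e-6)
  }

  # sharp one-hot rows gain entropy and lose their peak
  S <- diag(6)
  P <- gaussian_prune(S, ker)
  for (rr in 1:6) {
    expect_lt(max(P[rr, ]), 1)
    expect_gt(entropy_ref(P[rr, ]), entropy_ref(S[rr, ]))
  }

  # kernels larger than the matrix are cropped and renormalized
  small <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  ker5 <- build_gaussian_kernel(gaussian_kernel_spec(size = 5))
  out <- gaussian_prune(small, ker5)
  expect_equal(rowSums(out), c(1, 1), tolerance = 1e-12)
})

test_that("gcn_layer implements degree-normalized propagation with self-loops", {
  set.seed(33)
  H <- matrix(stats::rnorm(4 * 6), 4, 6)
  W <- matrix(stats::rnorm(6 * 5, sd = 0.5), 6, 5)

  # A = 0: pure per-node transform sigma(HW)
  out0 <- gcn_layer(H, matrix(0, 4, 4), W, activation = "relu")
  expect_equal(out0, pmax(H %*% W, 0))

  # identity everything: layer is the identity map
  expect_equal(gcn_layer(H, matrix(0, 4, 4), diag(6), activation = "identity"),
               H)

  # random row-stochastic A: degrees are all 2, matches hand computation
  A <- matrix(stats::runif(16), 4, 4); A <- A / rowSums(A)
  fw <- relgcn:::gcn_layer_forward(H, A, W, "relu")
  expect_equal(fw$deg, rep(2, 4), tolerance = 1e-12)
  ref <- pmax(((A + diag(4)) / 2) %*% H %*% W, 0)
  expect_equal(fw$out, ref, tolerance = 1e-12)

  expect_error(gcn_layer(H, matrix(-1, 4, 4), W), "non-negative")
})

test_that("gcn_layer is permutation-equivariant", {
  set.seed(44)
  for (i in 1:5) {
    H <- matrix(stats::rnorm(5 * 4), 5, 4)
    A <- matrix(stats::runif(25), 5, 5)
    W <- matrix(stats::rnorm(4 * 4), 4, 4)
    perm <- sample(5)
    out <- gcn_layer(H, A, W)
    out_p <- gcn_layer(H[perm, ], A[perm, perm], W)
    expect_equal(out_p, out[perm, ], tolerance = 1e-12)
  }
})

test_that("the full processor composes heads, pruning and mixing correctly", {
  set.seed(55)
  h <- matrix(stats::rnorm(5 * 8), 5, 8)
  params <- list(
    attn = list(list(Wq = matrix(stats::rnorm(8 * 8, sd = .4), 8, 8),
                     Wk = matrix(stats::rnorm(8 * 8, sd = .4), 8, 8))),
    gcn = list(list(matrix(stats::rnorm(8 * 8, sd = .4), 8, 8))),
    mix = list(W = diag(8), b = numeric(8)))

  # one head, pruning off, one layer, identity mix: equals the bare pipeline
  out <- feature_process(h, params, use_pruning = FALSE)
  S <- attention_adjacency(h, params$attn[[1]]$Wq, params$attn[[1]]$Wk)
  expect_equal(out, gcn_layer(h, S, params$gcn[[1]][[1]]))

  # pruning changes the result on sharp attention
  sharp_params <- params
  sharp_params$attn[[1]]$Wq <- 10 * params$attn[[1]]$Wq
  sharp_params$attn[[1]]$Wk <- 10 * params$attn[[1]]$Wk
  a <- feature_process(h, sharp_params, use_pruning = FALSE)
  b <- feature_process(h, sharp_params, use_pruning = TRUE)
  expect_gt(max(abs(a - b)), 1e-8)

  # identity ablation bypasses everything
  expect_identical(feature_process(h, params, use_pruning = FALSE,
                                   use_feature_capture = FALSE), h)
  expect_error(feature_process(h, params, use_pruning = TRUE,
                               use_feature_capture = FALSE),
               "contradictory")

  # residual shortcut adds h
  res <- feature_process(h, params, use_pruning = FALSE, residual = TRUE)
  expect_equal(res, out + h, tolerance = 1e-12)

  # output width follows the mix regardless of head count / depth
  p2 <- list(
    attn = list(list(Wq = matrix(.1, 8, 4), Wk = matrix(.2, 8, 4)),
                list(Wq = matrix(.3, 8, 4), Wk = matrix(-.1, 8, 4))),
    gcn = list(list(matrix(.1, 8, 6), matrix(.1, 6, 6)),
               list(matrix(.2, 8, 6), matrix(-.1, 6, 6))),
    mix = list(W = matrix(.1, 12, 7), b = numeric(7)))
  expect_identical(dim(feature_process(h, p2)), c(5L, 7L))
})

test_that("row-stochasticity survives the attention -> pruning pipeline", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    h <- matrix(stats::rnorm(n * 6, sd = 2), n, 6)
    Wq <- matrix(stats::rnorm(6 * 3), 6, 3)
    Wk <- matrix(stats::rnorm(6 * 3), 6, 3)
    S <- attention_adjacency(h, Wq, Wk)
    A <- gaussian_prune(S)
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
})

test_that("smoothing never decreases row entropy of attention matrices", {
  set.seed(77)
  ker <- build_gaussian_kernel(gaussian_kernel_spec(size = 3))
  for (i in 1:30) {
    n <- sample(3:10, 1)
    # sharpened random attention (peaked rows)
    L <- matrix(stats::rnorm(n * n, sd = 3), n, n)
    S <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    fw <- relgcn:::gaussian_prune_forward(S, ker)
    # pre-renormalization convolution is an averaging: compare row entropies
    for (rr in seq_len(n)) {
      expect_gte(entropy_ref(fw$A[rr, ]) - entropy_ref(S[rr, ]), -1e-4)
    }
  }
})
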