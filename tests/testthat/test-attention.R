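ns <- asNamespace("esagraph")

test_that("masked_sdpa matches the scalar-loop oracle and its closed cases", {
  set.seed(1)
  V <- matrix(rnorm(8), 4, 2)
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rnorm(12), 4, 3)

  # additive-diagonal-only mask: every token attends only to itself
  M <- matrix(esa_neg_value(), 4, 4)
  diag(M) <- 0
  expect_equal(masked_sdpa(Q, K, V, M), V, tolerance = 1e-12)

  # zero queries, zero mask: uniform softmax -> column means of V
  out <- masked_sdpa(matrix(0, 4, 3), K, V)
  expect_equal(out, matrix(colMeans(V), 4, 2, byrow = TRUE))

  # small seed-fixed case vs the scalar loop
  M2 <- matrix(c(0, esa_neg_value(), 0, 0), 2, 2)
  Q2 <- matrix(rnorm(4), 2, 2); K2 <- matrix(rnorm(4), 2, 2)
  V2 <- matrix(rnorm(4), 2, 2)
  expect_equal(masked_sdpa(Q2, K2, V2, M2), oracle_sdpa(Q2, K2, V2, M2),
               tolerance = 1e-6)

  expect_error(masked_sdpa(Q, K[, 1:2], V), "ncol")

  # softmax rows over real tokens sum to 1
  sc <- masked_sdpa(Q, K, V, return_scores = TRUE)$scores
  expect_equal(rowSums(sc), rep(1, 4), tolerance = 1e-6)
})

test_that("multi-head attention equals explicit per-head slicing", {
  set.seed(2)
  d <- 4L
  p <- ns$multihead_init(d)
  X <- matrix(rnorm(5 * d), 5, d)
  M <- matrix(0, 5, 5)
  M[1, 3] <- esa_neg_value()

  # h = 1: projected masked_sdpa
  out1 <- ns$multihead_fwd(X, X, M, p, h = 1L)$out
  q <- X %*% p$Wq$W; k <- X %*% p$Wk$W; v <- X %*% p$Wv$W
  expect_equal(out1, masked_sdpa(q, k, v, M) %*% p$Wo$W, tolerance = 1e-10)

  # h = 2: manual slice computation
  out2 <- ns$multihead_fwd(X, X, M, p, h = 2L)$out
  concat <- matrix(0, 5, d)
  for (i in 1:2) {
    cols <- ((i - 1) * 2 + 1):(i * 2)
    concat[, cols] <- masked_sdpa(q[, cols], k[, cols], v[, cols], M)
  }
  expect_equal(out2, concat %*% p$Wo$W, tolerance = 1e-10)

  # permuting keys/values together with mask columns permutes nothing
  perm <- c(3, 1, 5, 2, 4)
  out_p <- ns$multihead_fwd(X, X[perm, ], M[, perm], p, h = 2L)$out
  expect_equal(out_p, out2, tolerance = 1e-10)

  expect_error(ns$multihead_fwd(X, X, NULL, p, h = 3L), "%%")
})

test_that("MAB with zeroed projections reduces to its residual path", {
  set.seed(3)
  d <- 6L
  p <- ns$mab_init(d)
  p$att$Wo$W[] <- 0; p$att$Wo$b[] <- 0
  p$mlp$fc2$W[] <- 0; p$mlp$fc2$b[] <- 0
  X <- matrix(rnorm(4 * d), 4, d)
  M <- matrix(0, 4, 4)
  # pre-norm residual runs from the normalized input (H = Xbar + MH(Xbar)),
  # so killing both output projections leaves exactly LayerNorm(X)
  ln <- t(apply(X, 1, function(r)
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(mab(X, M, p, heads = 2L), ln, tolerance = 1e-12)
  # post-norm blocks residual from X itself; zeroed projections give
  # LayerNorm(LayerNorm(X))
  expect_equal(mab(X, M, p, heads = 2L, placement = "post"),
               t(apply(ln, 1, function(r)
                 (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5))),
               tolerance = 1e-10)
})

test_that("MAB matches a hand-unrolled step-by-step evaluation", {
  set.seed(4)
  d <- 4L; L <- 3L
  p <- ns$mab_init(d)
  X <- matrix(rnorm(L * d), L, d)
  M <- matrix(0, L, L); M[2, 1] <- esa_neg_value()

  # manual: Xbar = LayerNorm(X); H = Xbar + MH(Xbar); out = H + MLP(LN(H))
  ln <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1, function(r) g * (r - mean(r)) / sqrt(mean((r - mean(r))^2)
                                                       + eps) + b))
  }
  xbar <- ln(X, p$norm1$gamma, p$norm1$beta)
  q <- sweep(xbar %*% p$att$Wq$W, 2, p$att$Wq$b, "+")
  k <- sweep(xbar %*% p$att$Wk$W, 2, p$att$Wk$b, "+")
  v <- sweep(xbar %*% p$att$Wv$W, 2, p$att$Wv$b, "+")
  concat <- matrix(0, L, d)
  for (i in 1:2) {
    cols <- ((i - 1) * 2 + 1):(i * 2)
    concat[, cols] <- oracle_sdpa(q[, cols], k[, cols], v[, cols], M)
  }
  mh <- sweep(concat %*% p$att$Wo$W, 2, p$att$Wo$b, "+")
  h <- xbar + mh              # Eq-style pre-norm: residual from Xbar
  hbar <- ln(h, p$norm2$gamma, p$norm2$beta)
  pre <- sweep(hbar %*% p$mlp$fc1$W, 2, p$mlp$fc1$b, "+")
  act <- pre * pnorm(pre)
  out_manual <- h + sweep(act %*% p$mlp$fc2$W, 2, p$mlp$fc2$b, "+")

  expect_equal(mab(X, M, p, heads = 2L), out_manual, tolerance = 1e-8)
  # output shape equals input shape
  expect_equal(dim(mab(X, M, p, heads = 2L)), dim(X))
})

test_that("SAB is exactly MAB with a zero mask", {
  set.seed(5)
  d <- 8L
  p <- ns$mab_init(d)
  X <- matrix(rnorm(6 * d), 6, d)
  expect_identical(sab(X, p, heads = 2L),
                   mab(X, matrix(0, 6, 6), p, heads = 2L))
  # per-head, post-norm, gated variants agree too
  p2 <- ns$mab_init(d, mlp_variant = "gated")
  expect_identical(sab(X, p2, heads = 4L, placement = "post"),
                   mab(X, matrix(0, 6, 6), p2, heads = 4L,
                       placement = "post"))
})

test_that("PMA is invariant to token order and handles the edge cases", {
  set.seed(6)
  d <- 8L; L <- 7L
  p <- ns$pma_init(d, k = 4L, p_sabs = 1L)
  Z <- matrix(rnorm(L * d), L, d)
  pad <- rep(TRUE, L)
  out <- ns$pma_fwd_one(Z, pad, p, h = 2L)$out
  expect_equal(dim(out), c(4L, d))

  for (rep in 1:5) {
    perm <- sample(L)
    out_p <- ns$pma_fwd_one(Z[perm, ], pad, p, h = 2L)$out
    expect_equal(out_p, out, tolerance = 1e-5)
  }

  # single real token: cross-attention weight is 1 for every seed
  z1 <- matrix(rnorm(d), 1, d)
  r <- ns$multihead_fwd(p$seeds, z1, NULL, p$att, h = 2L, record = TRUE)
  expect_true(all(abs(r$scores - 1) < 1e-12))

  # k = 32 seeds -> 32 output rows
  p32 <- ns$pma_init(d, k = 32L, p_sabs = 0L)
  expect_equal(nrow(ns$pma_fwd_one(Z, pad, p32, h = 2L)$out), 32L)
})

test_that("pool_seeds: mean default, sum differs by factor k", {
  m <- rbind(c(1, 2), c(3, 4))
  expect_equal(pool_seeds(m), c(2, 3))
  expect_equal(pool_seeds(m, "sum"), c(4, 6))
  expect_equal(pool_seeds(m, "sum"), 2 * pool_seeds(m, "mean"))
  # k = 1 is the identity
  expect_equal(pool_seeds(rbind(c(5, 6))), c(5, 6))
  # mean of two identical rows is that row
  expect_equal(pool_seeds(rbind(c(1, 1), c(1, 1))), c(1, 1))
})

test_that("padded keys are excluded even in unmasked (S) blocks", {
  set.seed(7)
  d <- 6L
  p <- ns$mab_init(d)
  X <- matrix(rnorm(4 * d), 4, d)
  pad <- c(TRUE, TRUE, TRUE, FALSE)
  r <- ns$multihead_fwd(X, X, ns$pad_key_mask(pad), p$att, h = 2L,
                        record = TRUE)
  expect_true(all(r$scores[, , 4] < 1e-12))
  expect_equal(apply(r$scores, c(1, 2), sum), matrix(1, 2, 4),
               tolerance = 1e-6)
})
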