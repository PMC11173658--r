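test_that("cross-view InfoNCE has its closed forms", {
  # singleton drug set: the positive is the whole denominator
  Z <- matrix(c(1, 2), 1, 2)
  expect_equal(info_nce_views(Z, Z, 0.05), 0, tolerance = 1e-9)
  # identical embeddings in both views, all rows equal: log |D| at any tau
  for (tau in c(0.05, 0.5, 5)) {
    n <- 7
    Z <- matrix(rep(c(1, 1, 0), each = n), n, 3)
    expect_equal(info_nce_views(Z, Z, tau), log(n), tolerance = 1e-9)
  }
  expect_error(info_nce_views(matrix(0, 2, 2), matrix(1, 2, 2), 0.1),
               "zero-norm")
})

test_that("InfoNCE matches a per-pair oracle loop", {
  set.seed(13)
  n <- 4; d <- 3; tau <- 0.2
  A <- matrix(rnorm(n * d), n, d)
  B <- matrix(rnorm(n * d), n, d)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  l1 <- l2 <- 0
  for (i in 1:n) {
    den1 <- den2 <- 0
    for (k in 1:n) {
      den1 <- den1 + exp(cosine(A[i, ], B[k, ]) / tau)
      den2 <- den2 + exp(cosine(B[i, ], A[k, ]) / tau)
    }
    l1 <- l1 - log(exp(cosine(A[i, ], B[i, ]) / tau) / den1)
    l2 <- l2 - log(exp(cosine(B[i, ], A[i, ]) / tau) / den2)
  }
  expect_equal(info_nce_views(A, B, tau), (l1 + l2) / (2 * n),
               tolerance = 1e-6)
})

test_that("InfoNCE is invariant to a common orthogonal rotation", {
  set.seed(14)
  n <- 5; d <- 4
  A <- matrix(rnorm(n * d), n, d)
  B <- matrix(rnorm(n * d), n, d)
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  expect_equal(info_nce_views(A %*% Q, B %*% Q, 0.1),
               info_nce_views(A, B, 0.1), tolerance = 1e-9)
})

test_that("supervised contrastive loss has its closed forms", {
  # N identical embeddings, all the same event: log(N - 1)
  for (N in c(3, 6)) {
    emb <- matrix(rep(c(1, 2, 3), each = N), N, 3)
    expect_equal(supervised_contrastive(emb, rep(1, N), 0.05), log(N - 1),
                 tolerance = 1e-9)
  }
  # every anchor's class unique: no positives, loss 0
  set.seed(15)
  emb <- matrix(rnorm(12), 4, 3)
  expect_equal(supervised_contrastive(emb, 1:4, 0.1), 0)
  expect_warning(out <- supervised_contrastive(matrix(1, 1, 3), 1, 0.1),
                 "size")
  expect_equal(out, 0)
})

test_that("supervised contrastive loss matches a triple-loop oracle", {
  set.seed(16)
  n <- 6; d <- 4; tau <- 0.3
  emb <- matrix(rnorm(n * d), n, d)
  labels <- c(1, 2, 1, 3, 2, 1)
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  total <- 0; n_anchor <- 0
  for (i in 1:n) {
    pos <- setdiff(which(labels == labels[i]), i)
    if (!length(pos)) next
    n_anchor <- n_anchor + 1
    den <- 0
    for (u in setdiff(1:n, i)) den <- den + exp(cosine(emb[i, ], emb[u, ]) / tau)
    s <- 0
    for (m in pos) s <- s - log(exp(cosine(emb[i, ], emb[m, ]) / tau) / den)
    total <- total + s / length(pos)
  }
  expect_equal(supervised_contrastive(emb, labels, tau), total / n_anchor,
               tolerance = 1e-6)
})

test_that("prediction loss covers the perfect, uniform and hand cases", {
  onehot <- diag(3)
  expect_equal(prediction_loss(onehot, 1:3), 0, tolerance = 1e-9)
  E <- 5
  unif <- matrix(1 / E, 4, E)
  expect_equal(prediction_loss(unif, c(1, 3, 5, 2)), log(E), tolerance = 1e-9)
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(prediction_loss(probs, c(1, 2)),
               -(log(0.7) + log(0.8)) / 2, tolerance = 1e-12)
  # zero probability at the true class is clipped, not infinite
  expect_true(is.finite(prediction_loss(rbind(c(0, 1)), 1L)))
})

test_that("the total loss combines terms as L_s + alpha (L_uc + L_sc)", {
  expect_equal(total_loss(2, 5, 7, 0), 2)
  expect_equal(total_loss(1, 0, 0, 1), 1)
  expect_equal(total_loss(1, 2, 3, 0.1), 1.5)
})

test_that("all loss terms are nonnegative on random inputs", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(3:6, 1); d <- 4
    A <- matrix(rnorm(n * d), n, d)
    B <- matrix(rnorm(n * d), n, d)
    expect_gte(info_nce_views(A, B, 0.2), 0)
    labels <- sample(1:2, n, replace = TRUE)
    expect_gte(suppressWarnings(supervised_contrastive(A, labels, 0.2)), 0)
    P <- softmax_rows(matrix(rnorm(n * 3), n, 3))
    expect_gte(prediction_loss(P, sample(1:3, n, replace = TRUE)), 0)
  }
})
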