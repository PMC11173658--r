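test_that("feature transformation is an elementwise affine map through ELU", {
  X <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  W0 <- matrix(0, 3, 2)
  expect_equal(transform_features(X, W0, c(0, 0)), matrix(0, 2, 2))
  # identical feature rows give identical embeddings
  X2 <- rbind(X[1, ], X[1, ])
  set.seed(1)
  W <- matrix(rnorm(6), 3, 2)
  H <- transform_features(X2, W, c(0.1, -0.2))
  expect_equal(H[1, ], H[2, ])
  # scalar oracle on a 2x2 case
  Xs <- matrix(c(1, 2, 3, 4), 2, 2)
  Ws <- matrix(c(0.5, -1, 0.25, 2), 2, 2)
  b <- c(0.1, -0.3)
  Hs <- transform_features(Xs, Ws, b)
  for (i in 1:2) for (jj in 1:2) {
    z <- sum(Xs[i, ] * Ws[, jj]) + b[jj]
    expect_equal(Hs[i, jj], if (z > 0) z else exp(z) - 1)
  }
  expect_error(transform_features(matrix(NaN, 1, 1), matrix(1), 0), "finite")
})

test_that("graph attention matches the scalar oracle on a path graph", {
  set.seed(7)
  n <- 4; d <- 4; H <- 2
  adj <- matrix(0, n, n)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[3, 4] <- adj[4, 3] <- 1
  h <- matrix(rnorm(n * d), n, d)
  gp <- list(a = lapply(1:H, function(k) matrix(rnorm(2 * d), 2 * d, 1)),
             W = lapply(1:H, function(k) matrix(rnorm(d * d / H), d, d / H)),
             b = rnorm(d / H), ps = 0.25)
  Z <- gat_encode(adj, h, gp)
  expect_equal(Z, oracle_gat(adj, h, gp), tolerance = 1e-6)
})

test_that("attention weights are a distribution over each neighborhood", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
    adj <- pmax(adj, t(adj)); diag(adj) <- 0
    d <- 4
    h <- matrix(rnorm(n * d), n, d)
    gp <- list(a = lapply(1:2, function(k) matrix(rnorm(2 * d), 2 * d, 1)),
               W = lapply(1:2, function(k) matrix(rnorm(d * 2), d, 2)),
               b = rnorm(2), ps = 0.25)
    res <- gat_encode(adj, h, gp, return_attention = TRUE)
    A <- adj; diag(A) <- 1
    for (al in res$attention) {
      expect_equal(rowSums(al), rep(1, n), tolerance = 1e-6)
      expect_true(all(al[A == 0] == 0))
    }
    # single-neighbor node: attention concentrates fully
    iso <- which(rowSums(adj) == 0)
    for (i in iso) expect_equal(res$attention[[1]][i, i], 1)
  }
})

test_that("semantic fusion matches the scalar oracle and normalizes beta", {
  set.seed(9)
  n <- 5; d <- 4
  sp <- list(W1 = matrix(rnorm(d * d), d, d), b1 = rnorm(d), q1 = rnorm(d))
  Z_list <- lapply(1:3, function(g) matrix(rnorm(n * d), n, d))
  res <- semantic_fuse(Z_list, sp)
  orc <- oracle_semantic(Z_list, sp)
  expect_equal(res$beta, orc$beta, tolerance = 1e-6)
  expect_equal(res$Z_F, orc$Z_F, tolerance = 1e-6)
  expect_equal(sum(res$beta), 1, tolerance = 1e-9)

  # singleton list: beta = 1, Z_F = Z
  one <- semantic_fuse(Z_list[1], sp)
  expect_equal(one$beta, 1)
  expect_equal(one$Z_F, Z_list[[1]])

  # identical matrices: uniform weights
  same <- semantic_fuse(list(Z_list[[1]], Z_list[[1]], Z_list[[1]]), sp)
  expect_equal(same$beta, rep(1 / 3, 3), tolerance = 1e-9)
  expect_error(semantic_fuse(list(), sp), "empty")
})

test_that("beta is permutation-equivariant and renormalizes after a drop", {
  set.seed(10)
  n <- 4; d <- 4
  sp <- list(W1 = matrix(rnorm(d * d), d, d), b1 = rnorm(d), q1 = rnorm(d))
  Z_list <- lapply(1:4, function(g) matrix(rnorm(n * d), n, d))
  b1 <- semantic_fuse(Z_list, sp)$beta
  perm <- c(3, 1, 4, 2)
  b2 <- semantic_fuse(Z_list[perm], sp)$beta
  expect_equal(b2, b1[perm], tolerance = 1e-9)
  b3 <- semantic_fuse(Z_list[-2], sp)$beta
  expect_equal(sum(b3), 1, tolerance = 1e-9)
  expect_equal(b3, b1[-2] / sum(b1[-2]), tolerance = 1e-9)
})

test_that("semantic weights sum to one across random parameter draws", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:6, 1); d <- 4
    l <- sample(2:5, 1)
    sp <- list(W1 = matrix(rnorm(d * d), d, d), b1 = rnorm(d), q1 = rnorm(d))
    Z_list <- lapply(seq_len(l), function(g) matrix(rnorm(n * d), n, d))
    beta <- semantic_fuse(Z_list, sp)$beta
    expect_equal(sum(beta), 1, tolerance = 1e-6)
    expect_true(all(beta >= 0))
  }
})

test_that("average-view encoding uses the support of the averaged adjacency", {
  set.seed(12)
  hg <- random_hg(n_drugs = 6, n_attr = 4, n_ppi = 2, seed = 12)
  sgs <- build_subgraphs(hg)
  M_C <- average_view(sgs)
  expect_true(all(M_C >= 0 & M_C <= 1))
  d <- 4
  h <- matrix(rnorm(6 * d), 6, d)
  gp <- list(a = lapply(1:2, function(k) matrix(rnorm(2 * d), 2 * d, 1)),
             W = lapply(1:2, function(k) matrix(rnorm(d * 2), d, 2)),
             b = rnorm(2), ps = 0.25)
  Z <- encode_average_view(M_C, h, gp)
  expect_equal(Z, gat_encode((M_C > 0) * 1, h, gp))
  expect_true(all(is.finite(Z)))
})
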