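test_that("feature masking removes whole attribute columns, not X entries", {
  hg <- random_hg(n_drugs = 10, n_attr = 10, n_ppi = 4, seed = 5)
  expect_identical(mask_features(hg, 0), hg)
  set.seed(1)
  hg2 <- mask_features(hg, 0.2)
  for (nm in names(hg$M)) {
    zeroed <- sum(colSums(hg$M[[nm]]) > 0 & colSums(hg2$M[[nm]]) == 0)
    removed <- round(0.2 * ncol(hg$M[[nm]]))
    expect_lte(zeroed, removed)  # some sampled columns may already be empty
    expect_true(all(hg2$M[[nm]] <= hg$M[[nm]]))
  }
  expect_identical(hg2$X, hg$X)
  # caller's graph untouched
  expect_true(sum(hg$M$DC) > sum(hg2$M$DC) || sum(hg$M$DC) == 0)
})

test_that("feature masking zeroes exactly round(af * n) columns per type", {
  hg <- make_hg(matrix(1, 4, 10), matrix(1, 4, 10))
  set.seed(2)
  hg2 <- mask_features(hg, 0.2)
  expect_equal(sum(colSums(hg2$M$DC) == 0), 2)
  expect_equal(sum(colSums(hg2$M$DP) == 0), 2)
  # PPI rows of removed target proteins are zeroed
  hgp <- make_hg(matrix(1, 4, 2), matrix(1, 4, 2),
                 M_PP = matrix(c(0, 1, 1, 0), 2, 2))
  set.seed(3)
  hgp2 <- mask_features(hgp, 0.5)
  gone <- which(colSums(hgp2$M$DP) == 0)
  expect_length(gone, 1)
  expect_equal(sum(hgp2$M_PP[gone, ]), 0)
  expect_equal(sum(hgp2$M_PP[, gone]), 0)
})

test_that("removing a shared attribute deletes the corresponding paths", {
  # single shared substructure between D1, D2
  hg <- make_hg(matrix(c(1, 1), 2, 1), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(count_paths(hg, "DCD")[1, 2], 1)
  # the cap never removes the last node of a type (one warning per capped type)
  w <- capture_warnings(hg2 <- mask_features(hg, 0.9))
  expect_match(w, "capping", all = TRUE)
  expect_gt(sum(hg2$M$DC), 0)
  hg3 <- make_hg(matrix(c(1, 0, 1, 1), 2, 2), matrix(1, 2, 1))
  set.seed(7)
  hg4 <- suppressWarnings(mask_features(hg3, 0.5))
  expect_equal(count_paths(hg4, "DCD"), oracle_count_paths(hg4, "DCD"))
})

test_that("edge masking removes exactly round(ae * m) edges per sub-graph", {
  hg <- random_hg(n_drugs = 12, n_attr = 6, n_ppi = 4, seed = 6)
  sgs <- build_subgraphs(hg)
  expect_identical(mask_edges(sgs, 0), sgs)
  set.seed(4)
  sgs2 <- mask_edges(sgs, 0.3)
  for (nm in sgs$names) {
    m <- sum(sgs$graphs[[nm]]) / 2
    m2 <- sum(sgs2$graphs[[nm]]) / 2
    expect_equal(m2, m - round_half_up(0.3 * m), info = nm)
    expect_equal(sgs2$graphs[[nm]], t(sgs2$graphs[[nm]]))
    expect_equal(diag(sgs2$graphs[[nm]]), rep(0, 12))
  }
})

test_that("edge survival frequency matches 1 - ae", {
  A <- matrix(0, 6, 6)
  A[upper.tri(A)] <- 1
  A <- A + t(A)
  sgs <- structure(list(graphs = list(G = A), names = "G", K = c(G = 3L)),
                   class = "subgraph_set")
  ae <- 0.4
  m <- sum(A) / 2
  set.seed(9)
  surv <- matrix(0, 6, 6)
  n_rep <- 400
  for (r in seq_len(n_rep)) surv <- surv + mask_edges(sgs, ae)$graphs$G
  rate <- surv[upper.tri(surv)] / n_rep
  keep_frac <- (m - round_half_up(ae * m)) / m
  ci <- 2.58 * sqrt(keep_frac * (1 - keep_frac) / n_rep)
  expect_true(all(abs(rate - keep_frac) < ci + 0.01))
})

test_that("sub-graph drop removes exactly one graph with probability ag", {
  hg <- random_hg(n_drugs = 8, n_attr = 4, n_ppi = 2, seed = 8)
  sgs <- build_subgraphs(hg)
  expect_identical(mask_subgraph(sgs, 0), sgs)
  set.seed(5)
  expect_equal(length(mask_subgraph(sgs, 1)$graphs), length(sgs$graphs) - 1L)
  one <- build_subgraphs(hg, specs = "DCD")
  set.seed(6)
  expect_warning(kept <- mask_subgraph(one, 1), "only one")
  expect_equal(length(kept$graphs), 1L)
})

test_that("the epoch pipeline respects ablation modes and determinism", {
  hg <- random_hg(n_drugs = 10, n_attr = 6, n_ppi = 3, seed = 10)
  sgs <- build_subgraphs(hg)
  none <- aug_config(af = 0.3, ae = 0.3, ag = 1, mode = "none", seed = 1)
  expect_identical(build_augmented_set(hg, sgs, none, 1), sgs)

  fonly <- aug_config(af = 0.3, ae = 0.5, ag = 1, mode = "f", seed = 1)
  out <- build_augmented_set(hg, sgs, fonly, 1)
  expect_equal(length(out$graphs), length(sgs$graphs))  # no drop
  expect_equal(out$K, sgs$K)  # K fixed from the clean graph

  eonly <- aug_config(af = 0.5, ae = 0.3, ag = 1, mode = "e", seed = 1)
  out_e <- build_augmented_set(hg, sgs, eonly, 1)
  for (nm in sgs$names) {
    m <- sum(sgs$graphs[[nm]]) / 2
    expect_equal(sum(out_e$graphs[[nm]]) / 2, m - round_half_up(0.3 * m))
  }

  gonly <- aug_config(af = 0.5, ae = 0.5, ag = 1, mode = "g", seed = 1)
  out_g <- build_augmented_set(hg, sgs, gonly, 1)
  expect_equal(length(out_g$graphs), length(sgs$graphs) - 1L)
  for (nm in out_g$names) expect_identical(out_g$graphs[[nm]], sgs$graphs[[nm]])

  full <- aug_config(af = 0.2, ae = 0.3, ag = 0.5, mode = "full", seed = 3)
  a <- build_augmented_set(hg, sgs, full, 4)
  b <- build_augmented_set(hg, sgs, full, 4)
  expect_identical(a, b)  # same seed and epoch -> identical corruption
  # outputs stay binary/symmetric/zero-diagonal
  for (g in a$graphs) {
    expect_true(all(g %in% c(0, 1)))
    expect_equal(g, t(g))
    expect_equal(sum(diag(g)), 0)
  }
})
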