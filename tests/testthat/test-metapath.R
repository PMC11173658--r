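test_that("meta-path counts match hand enumeration on the worked example", {
  # D1 ~ {C1, C2}, D2 ~ {C2}
  hg <- make_hg(matrix(c(1, 0, 1, 1), 2, 2), matrix(1, 2, 1))
  C <- count_paths(hg, "DCD")
  expect_equal(C, matrix(c(2, 1, 1, 1), 2, 2))
  S <- pathsim(C)
  expect_equal(S[1, 2], 2 / 3)
  expect_equal(diag(S), c(1, 1))
})

test_that("a drug with no attributes has zero path counts", {
  hg <- make_hg(matrix(c(1, 0, 1, 0), 2, 2), matrix(1, 2, 1))
  C <- count_paths(hg, "DCD")
  expect_equal(C[2, ], c(0, 0))
  S <- pathsim(C)
  expect_equal(S[2, 2], 0)  # zero-denominator guard
})

test_that("DPPD counts walks through PPI edges and protein self-loops", {
  # D1 ~ P1, D2 ~ P2, PPI {P1-P2}
  hg <- make_hg(matrix(1, 2, 1), matrix(c(1, 0, 0, 1), 2, 2),
                M_PP = matrix(c(0, 1, 1, 0), 2, 2))
  C <- count_paths(hg, "DPPD")
  expect_equal(C[1, 2], 1)
  expect_equal(diag(C), c(1, 1))  # self-loop gives p_ii >= target count
  expect_equal(pathsim(C)[1, 1], 1)
})

test_that("counts and PathSim match the exhaustive oracle on random HGs", {
  for (seed in 1:12) {
    hg <- random_hg(n_drugs = sample(3:10, 1), n_attr = sample(2:6, 1),
                    n_ppi = sample(0:5, 1), seed = seed)
    for (nm in available_metapaths(hg)) {
      C <- count_paths(hg, nm)
      expect_equal(C, oracle_count_paths(hg, nm), info = paste(seed, nm))
      expect_equal(pathsim(C), oracle_pathsim(C), info = paste(seed, nm))
    }
  }
})

test_that("PathSim never decreases when a shared attribute is added", {
  for (seed in 1:8) {
    hg <- random_hg(n_drugs = 6, n_attr = 4, n_ppi = 0, seed = seed)
    S0 <- pathsim(count_paths(hg, "DCD"))
    hg2 <- hg
    hg2$M$DC <- cbind(hg2$M$DC, shared = c(1, 1, rep(0, 4)))
    S1 <- pathsim(count_paths(hg2, "DCD"))
    expect_gte(S1[1, 2], S0[1, 2])
  }
})

test_that("default K is the mean neighbor count, floored at one", {
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- 0.5
  S[1, 3] <- S[3, 1] <- 0.4
  S[2, 4] <- S[4, 2] <- 0.3
  S[3, 4] <- S[4, 3] <- 0.2
  diag(S) <- 1
  expect_equal(default_topk(S), 2L)  # 8 nonzero off-diagonal entries / 4
  expect_equal(default_topk(diag(4)), 1L)
  Sc <- matrix(0.5, 5, 5); diag(Sc) <- 1
  expect_equal(default_topk(Sc), 4L)  # complete graph: K = n - 1
})

test_that("neighbor filtering keeps top-K with index tie-breaks and unions", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.9
  S[1, 3] <- S[3, 1] <- 0.4
  S[2, 3] <- S[3, 2] <- 0.8
  A <- neighbor_filter(S, 1)
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  # fewer nonzero similarities than K: keep all, zeros never selected
  S2 <- diag(3); S2[1, 2] <- S2[2, 1] <- 0.5
  A2 <- neighbor_filter(S2, 2)
  expect_equal(sum(A2), 2)
  expect_equal(neighbor_filter(diag(3), 2), matrix(0, 3, 3))
  # tie broken by smaller index
  S3 <- diag(3); S3[1, 2] <- S3[2, 1] <- 0.5; S3[1, 3] <- S3[3, 1] <- 0.5
  A3 <- neighbor_filter(S3, 1)
  expect_equal(A3[1, 2], 1)
})

test_that("per-drug selection degree is honored before symmetrization", {
  for (seed in 1:5) {
    set.seed(seed)
    S <- matrix(runif(49), 7, 7)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    K <- 3
    A <- neighbor_filter(S, K)
    for (i in 1:7) {
      nnz <- sum(S[i, -i] > 0)
      expect_gte(sum(A[i, ]), min(K, nnz))
    }
    expect_equal(A, t(A))
    expect_equal(diag(A), rep(0, 7))
  }
})

test_that("build_subgraphs respects available types and the noPPI variant", {
  hg <- random_hg(n_drugs = 8, n_attr = 4, n_ppi = 3, seed = 2)
  sgs <- build_subgraphs(hg)
  expect_equal(sgs$names, c("DCD", "DPD", "DED", "DTD", "DPPD"))
  # no pathway type (Dataset2 shape: C, P, E + PPI) -> l = 4
  hg2 <- hg
  hg2$M$DT <- NULL
  expect_equal(build_subgraphs(hg2)$names, c("DCD", "DPD", "DED", "DPPD"))
  # noPPI drops DPPD only
  sgs3 <- build_subgraphs(hg, use_ppi = FALSE)
  expect_false("DPPD" %in% sgs3$names)
  expect_equal(length(sgs3$graphs), 4L)
  expect_error(build_subgraphs(hg, specs = character(0)), "no meta-paths")
  # single meta-path
  expect_equal(length(build_subgraphs(hg, specs = "DCD")$graphs), 1L)
})

test_that("sub-graphs serialize to edge lists with a manifest", {
  hg <- random_hg(n_drugs = 8, n_attr = 4, n_ppi = 3, seed = 4)
  sgs <- build_subgraphs(hg)
  dir <- withr::local_tempdir()
  write_subgraphs(sgs, dir, hg$drug_ids)
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_equal(man$metapath, sgs$names)
  ed <- read.delim(file.path(dir, "subgraph_DCD.tsv"), header = FALSE)
  expect_equal(nrow(ed), sum(sgs$graphs$DCD) / 2)
})

test_that("average view entries are sub-graph edge fractions", {
  g1 <- matrix(c(0, 1, 1, 0), 2, 2)
  g0 <- matrix(0, 2, 2)
  sgs <- structure(list(graphs = list(A = g1, B = g1, C = g0, D = g0, E = g0),
                        names = LETTERS[1:5], K = rep(1, 5)),
                   class = "subgraph_set")
  expect_equal(average_view(sgs)[1, 2], 0.4)
})
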