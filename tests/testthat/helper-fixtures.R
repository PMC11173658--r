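# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as scalar loops / exhaustive enumeration, independent
# of the matrix-algebra implementation paths they check.

# Build a drug_hg directly from matrices (bypasses file loading).
make_hg <- function(M_DC, M_DP, M_DE = NULL, M_DT = NULL, M_PP = NULL,
                    X = NULL, smiles = NULL) {
  n <- nrow(M_DC)
  drug_ids <- sprintf("d%d", seq_len(n))
  rownames(M_DC) <- rownames(M_DP) <- drug_ids
  if (is.null(colnames(M_DC))) colnames(M_DC) <- sprintf("c%d", seq_len(ncol(M_DC)))
  if (is.null(colnames(M_DP))) colnames(M_DP) <- sprintf("p%d", seq_len(ncol(M_DP)))
  M <- list(DC = M_DC, DP = M_DP)
  if (!is.null(M_DE)) {
    rownames(M_DE) <- drug_ids
    colnames(M_DE) <- sprintf("e%d", seq_len(ncol(M_DE)))
    M$DE <- M_DE
  }
  if (!is.null(M_DT)) {
    rownames(M_DT) <- drug_ids
    colnames(M_DT) <- sprintf("t%d", seq_len(ncol(M_DT)))
    M$DT <- M_DT
  }
  if (is.null(M_PP)) M_PP <- matrix(0, ncol(M_DP), ncol(M_DP))
  dimnames(M_PP) <- list(colnames(M_DP), colnames(M_DP))
  if (is.null(X)) X <- matrix(1, n, 3)
  rownames(X) <- drug_ids
  if (is.null(smiles)) smiles <- rep("CCO", n)
  structure(list(drug_ids = drug_ids, smiles = stats::setNames(smiles, drug_ids),
                 attr_ids = lapply(M, colnames), M = M, M_PP = M_PP, X = X,
                 vocab = NULL),
            class = "drug_hg")
}

# Random small heterogeneous graph for oracle-equivalence sweeps.
random_hg <- function(n_drugs = 8, n_attr = 5, n_ppi = 4, seed = 1,
                      with_et = TRUE) {
  set.seed(seed)
  rb <- function(nc, p = 0.4) matrix(rbinom(n_drugs * nc, 1, p), n_drugs, nc)
  M_DC <- rb(n_attr)
  M_DP <- rb(n_attr)
  np <- ncol(M_DP)
  M_PP <- matrix(0, np, np)
  if (n_ppi > 0 && np >= 2) {
    for (s in seq_len(n_ppi)) {
      pq <- sample(np, 2)
      M_PP[pq[1], pq[2]] <- M_PP[pq[2], pq[1]] <- 1
    }
  }
  make_hg(M_DC, M_DP,
          M_DE = if (with_et) rb(max(2, n_attr - 1)) else NULL,
          M_DT = if (with_et) rb(max(2, n_attr - 2)) else NULL,
          M_PP = M_PP)
}

# Exhaustive walk-enumeration oracle for meta-path instance counts.
oracle_count_paths <- function(hg, name) {
  n <- length(hg$drug_ids)
  out <- matrix(0, n, n)
  if (name == "DPPD") {
    M <- hg$M$DP
    A <- hg$M_PP + diag(nrow(hg$M_PP))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      cnt <- 0
      for (p in seq_len(ncol(M))) for (q in seq_len(ncol(M))) {
        if (M[i, p] == 1 && A[p, q] == 1 && M[j, q] == 1) cnt <- cnt + 1
      }
      out[i, j] <- cnt
    }
  } else {
    M <- hg$M[[c(DCD = "DC", DPD = "DP", DED = "DE", DTD = "DT")[[name]]]]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      cnt <- 0
      for (a in seq_len(ncol(M))) {
        if (M[i, a] == 1 && M[j, a] == 1) cnt <- cnt + 1
      }
      out[i, j] <- cnt
    }
  }
  out
}

# Per-pair PathSim oracle (2 c_ij / (c_ii + c_jj), zero-denominator guard,
# truncation at 1 as documented).
oracle_pathsim <- function(counts) {
  n <- nrow(counts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    den <- counts[i, i] + counts[j, j]
    out[i, j] <- if (den > 0) min(1, 2 * counts[i, j] / den) else 0
  }
  out
}

# Scalar brute-force evaluation of one multi-head attention encoding.
oracle_gat <- function(adj, h, gp) {
  n <- nrow(adj)
  d <- ncol(h)
  H <- length(gp$a)
  dh <- d / H
  A <- adj
  diag(A) <- 1
  Z <- matrix(0, n, 0)
  for (k in seq_len(H)) {
    a <- gp$a[[k]][, 1]
    Zk <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      nb <- which(A[i, ] > 0)
      e <- numeric(length(nb))
      for (t in seq_along(nb)) {
        x <- sum(a * c(h[i, ], h[nb[t], ]))
        e[t] <- if (x > 0) x else 0.2 * x
      }
      al <- exp(e - max(e))
      al <- al / sum(al)
      agg <- numeric(dh)
      for (t in seq_along(nb)) {
        agg <- agg + al[t] * as.numeric(h[nb[t], ] %*% gp$W[[k]])
      }
      agg <- agg + gp$b
      Zk[i, ] <- ifelse(agg > 0, agg, gp$ps * agg)
    }
    Z <- cbind(Z, Zk)
  }
  Z
}

# Scalar brute-force evaluation of semantic attention fusion.
oracle_semantic <- function(Z_list, sp) {
  e <- numeric(length(Z_list))
  for (g in seq_along(Z_list)) {
    Z <- Z_list[[g]]
    s <- numeric(ncol(Z))
    for (i in seq_len(nrow(Z))) {
      s <- s + tanh(as.numeric(Z[i, ] %*% sp$W1) + sp$b1)
    }
    s <- s / nrow(Z)
    e[g] <- sum(sp$q1 * s)
  }
  beta <- exp(e - max(e))
  beta <- beta / sum(beta)
  ZF <- matrix(0, nrow(Z_list[[1]]), ncol(Z_list[[1]]))
  for (g in seq_along(Z_list)) ZF <- ZF + beta[g] * Z_list[[g]]
  list(beta = beta, Z_F = ZF)
}

# Numerical gradient of f (scalar function of a flat numeric vector).
num_grad <- function(f, x, eps = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Small planted-structure dataset for learning smoke tests.
small_synth <- function(seed = 3, n_drugs = 40) {
  generate_synthetic(synth_config(n_drugs = n_drugs,
                                  n_attrs = c(C = 12, P = 10, E = 8, T = 6),
                                  pair_density = 0.3, seed = seed))
}
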