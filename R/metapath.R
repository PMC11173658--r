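# Meta-path instance counting, PathSim similarity, top-K neighbor filtering
# and per-meta-path drug sub-graphs.
#
# Meta-paths considered: DCD, DPD, DED, DTD (2-hop through shared chemical
# substructures, target proteins, enzymes, pathways) and DPPD (3-hop through
# interacting target proteins). PathSim between drugs i and j is
# s(i,j) = 2 p_ij / (p_ii + p_jj), the path-instance counts being entries of
# the incidence-chain product. For DPPD the protein-protein matrix is used
# with added self-loops (M_PP + I): the diagonal count then dominates the
# drug's target count, so s(i,i) = 1 holds and the denominator cannot vanish
# for target-bearing drugs.

METAPATH_ORDER <- c("DCD", "DPD", "DED", "DTD", "DPPD")

metapath_incidence <- c(DCD = "DC", DPD = "DP", DED = "DE", DTD = "DT",
                        DPPD = "DP")

#' Meta-paths constructible from a drug HG
#'
#' Returns the names of the available meta-paths in canonical order
#' {DCD, DPD, DED, DTD, DPPD}, restricted to attribute types present in `hg`.
#' With `use_ppi = FALSE` (the noPPI configuration) DPPD is omitted.
#'
#' @param hg a `drug_hg`.
#' @param use_ppi include the 3-hop DPPD meta-path?
#' @return character vector of meta-path names.
#' @export
available_metapaths <- function(hg, use_ppi = TRUE) {
  out <- character(0)
  for (nm in METAPATH_ORDER) {
    if (nm == "DPPD" && !use_ppi) next
    inc <- metapath_incidence[[nm]]
    if (!is.null(hg$M[[inc]]) && ncol(hg$M[[inc]]) > 0) out <- c(out, nm)
  }
  out
}

#' Count meta-path instances between every drug pair
#'
#' Counts are the incidence-chain product: DCD gives M_DC M_DC^T (and
#' analogously for DPD/DED/DTD); DPPD gives M_DP (M_PP + I) M_DP^T.
#'
#' @param hg a `drug_hg`.
#' @param name meta-path name.
#' @return symmetric integer |D| x |D| count matrix.
#' @export
count_paths <- function(hg, name) {
  inc <- metapath_incidence[[name]]
  if (is.null(inc)) stop(sprintf("unknown meta-path: %s", name))
  M <- hg$M[[inc]]
  if (is.null(M) || ncol(M) == 0L) {
    stop(sprintf("meta-path unavailable: %s (no %s relations)", name, inc))
  }
  if (name == "DPPD") {
    A <- hg$M_PP + diag(nrow(hg$M_PP))
    C <- M %*% A %*% t(M)
  } else {
    C <- tcrossprod(M)
  }
  unname(round(C))
}

#' PathSim similarity from path-instance counts
#'
#' s(i,j) = 2 c_ij / (c_ii + c_jj), with s(i,j) = 0 when the denominator is
#' zero, truncated at 1 (3-hop counts through protein interactions can exceed
#' the symmetric bound; see the methods vignette).
#'
#' @param counts symmetric count matrix from [count_paths()].
#' @return symmetric similarity matrix in `[0, 1]`.
#' @export
pathsim <- function(counts) {
  d <- diag(counts)
  denom <- outer(d, d, `+`)
  S <- ifelse(denom > 0, 2 * counts / pmax(denom, 1e-300), 0)
  S[denom == 0] <- 0
  pmin(S, 1)
}

#' Default neighborhood size K for a similarity matrix
#'
#' K is the average number of connections per drug under the meta-path:
#' the number of nonzero off-diagonal similarity entries divided by |D|,
#' rounded half away from zero, floored at 1.
#'
#' @param sim similarity matrix.
#' @return positive integer K.
#' @export
default_topk <- function(sim) {
  n <- nrow(sim)
  nz <- sum(sim > 0) - sum(diag(sim) > 0)
  max(1L, as.integer(round_half_up(nz / n)))
}

#' Top-K neighbor filtering of a similarity matrix
#'
#' Per drug, the K off-diagonal neighbors with largest nonzero similarity are
#' selected (ties broken by smaller drug index); zero similarities are never
#' selected even when fewer than K neighbors exist. The final adjacency is the
#' union-symmetrization of the per-drug selections, with zero diagonal.
#'
#' @param sim similarity matrix.
#' @param K neighborhood size, >= 1.
#' @return binary symmetric adjacency with zero diagonal.
#' @export
neighbor_filter <- function(sim, K) {
  stopifnot(K >= 1)
  n <- nrow(sim)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- 0
    cand <- which(s > 0)
    if (!length(cand)) next
    ord <- cand[order(-s[cand], cand)]
    sel <- ord[seq_len(min(K, length(ord)))]
    A[i, sel] <- 1
  }
  A <- pmax(A, t(A))
  diag(A) <- 0
  A
}

#' Build the set of meta-path-based drug sub-graphs
#'
#' For each available meta-path (in canonical order), composes
#' [count_paths()] -> [pathsim()] -> [default_topk()] (or an override) ->
#' [neighbor_filter()].
#'
#' @param hg a `drug_hg`.
#' @param specs meta-path names to build; default all available.
#' @param K_overrides optional named integer vector of per-meta-path K values.
#' @param use_ppi include DPPD (set FALSE for the noPPI variant)?
#' @return an object of class `subgraph_set`: list with `graphs` (binary
#'   adjacencies), `names`, and `K` (values used).
#' @export
build_subgraphs <- function(hg, specs = NULL, K_overrides = NULL, use_ppi = TRUE) {
  if (is.null(specs)) specs <- available_metapaths(hg, use_ppi = use_ppi)
  if (!length(specs)) stop("no meta-paths to build")
  specs <- METAPATH_ORDER[METAPATH_ORDER %in% specs]
  graphs <- list()
  Ks <- integer(0)
  for (nm in specs) {
    S <- pathsim(count_paths(hg, nm))
    K <- if (!is.null(K_overrides) && !is.na(K_overrides[nm] %||% NA)) {
      as.integer(K_overrides[[nm]])
    } else {
      default_topk(S)
    }
    graphs[[nm]] <- neighbor_filter(S, K)
    Ks[nm] <- K
  }
  structure(list(graphs = graphs, names = specs, K = Ks),
            class = "subgraph_set")
}

#' @export
print.subgraph_set <- function(x, ...) {
  cat(sprintf("meta-path sub-graph set (l = %d)\n", length(x$graphs)))
  for (nm in x$names) {
    cat(sprintf("  %s: K = %d, %d edges\n", nm, x$K[[nm]],
                sum(x$graphs[[nm]]) / 2))
  }
  invisible(x)
}

#' Serialize a sub-graph set as per-meta-path edge lists plus a manifest
#'
#' @param sgs a `subgraph_set`.
#' @param dir output directory.
#' @param drug_ids drug identifiers used for edge endpoints.
#' @return `dir`, invisibly.
#' @export
write_subgraphs <- function(sgs, dir, drug_ids) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(metapath = character(0), K = integer(0),
                         n_edges = integer(0))
  for (nm in sgs$names) {
    ed <- adj_to_edges(sgs$graphs[[nm]])
    utils::write.table(data.frame(a = drug_ids[ed[, 1]], b = drug_ids[ed[, 2]]),
                       file.path(dir, sprintf("subgraph_%s.tsv", nm)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    manifest <- rbind(manifest,
                      data.frame(metapath = nm, K = sgs$K[[nm]],
                                 n_edges = nrow(ed)))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Average graph view adjacency
#'
#' Mean of the sub-graph adjacencies: M_C = (1/l) sum_i M_DD^{P_i}; entries lie
#' in `[0, 1]` and give the fraction of meta-paths connecting each drug pair.
#'
#' @param sgs a `subgraph_set`.
#' @return |D| x |D| matrix in `[0, 1]`.
#' @export
average_view <- function(sgs) {
  Reduce(`+`, sgs$graphs) / length(sgs$graphs)
}
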