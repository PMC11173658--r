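# Three-level masking augmentation producing the corrupted sub-graph set used
# by the augmented contrastive view each training epoch:
#   level 1 (feature):   mask attribute nodes of the heterogeneous graph,
#   level 3 (sub-graph): with probability ag drop one sub-graph,
#   level 2 (edge):      mask edges of each surviving sub-graph.
# The perturbation order is feature -> sub-graph -> edge (the drop decision is
# taken before edge masking; the distribution of the result is unchanged).
# All functions are pure: inputs are never modified in place.

#' Augmentation configuration
#'
#' @param af feature-mask ratio in `[0, 1)`: fraction of attribute nodes
#'   removed per attribute type.
#' @param ae edge-mask ratio in `[0, 1)`: fraction of edges removed per
#'   sub-graph.
#' @param ag sub-graph-mask probability in `[0, 1]`.
#' @param mode one of "full", "none", "f", "e", "g" — enable all levels, none,
#'   or exactly one (the noMask/fMask/eMask/gMask ablations).
#' @param seed integer; a dedicated random stream derived from `seed` and the
#'   epoch index drives all masking.
#' @return a list of class `aug_config`.
#' @export
aug_config <- function(af = 0.2, ae = 0.3, ag = 0.2, mode = "full", seed = 1L) {
  stopifnot(af >= 0, af < 1, ae >= 0, ae < 1, ag >= 0, ag <= 1)
  mode <- match.arg(mode, c("full", "none", "f", "e", "g"))
  structure(list(af = af, ae = ae, ag = ag, mode = mode, seed = as.integer(seed)),
            class = "aug_config")
}

#' Level 1: mask attribute nodes of the drug HG
#'
#' For each attribute type independently, removes `round(af * n_type)`
#' attribute nodes chosen uniformly without replacement by zeroing their
#' incidence columns. The drug feature matrix X is untouched. PPI rows and
#' columns of removed target proteins are zeroed. Never removes all nodes of a
#' type (capped at n_type - 1 with a warning). Uses the current RNG state.
#'
#' @param hg a `drug_hg`.
#' @param af masking ratio in `[0, 1)`.
#' @return a corrupted copy of `hg`.
#' @export
mask_features <- function(hg, af) {
  stopifnot(af >= 0, af < 1)
  if (af == 0) return(hg)
  out <- hg
  for (nm in names(hg$M)) {
    n <- ncol(hg$M[[nm]])
    if (n == 0L) next
    k <- round_half_up(af * n)
    if (k >= n) {
      warning(sprintf("mask_features: capping removal at %d of %d %s nodes",
                      n - 1L, n, nm))
      k <- n - 1L
    }
    if (k <= 0) next
    cols <- sample.int(n, k)
    out$M[[nm]][, cols] <- 0
    if (nm == "DP") {
      out$M_PP[cols, ] <- 0
      out$M_PP[, cols] <- 0
    }
  }
  out
}

#' Level 2: mask edges of each sub-graph
#'
#' Per sub-graph, removes `round(ae * m)` of its m undirected edges uniformly
#' without replacement; symmetry and the zero diagonal are preserved. Uses the
#' current RNG state.
#'
#' @param sgs a `subgraph_set`.
#' @param ae masking ratio in `[0, 1)`.
#' @return a corrupted `subgraph_set`.
#' @export
mask_edges <- function(sgs, ae) {
  stopifnot(ae >= 0, ae < 1)
  if (ae == 0) return(sgs)
  out <- sgs
  for (nm in names(sgs$graphs)) {
    ed <- adj_to_edges(sgs$graphs[[nm]])
    m <- nrow(ed)
    if (m == 0L) next
    k <- round_half_up(ae * m)
    if (k <= 0) next
    drop <- sample.int(m, k)
    out$graphs[[nm]] <- edges_to_adj(ed[-drop, , drop = FALSE],
                                     nrow(sgs$graphs[[nm]]))
  }
  out
}

#' Level 3: drop one sub-graph with probability ag
#'
#' Samples r ~ Bernoulli(ag); if r = 1, exactly one uniformly chosen sub-graph
#' is removed from the set (skipped with a warning when only one sub-graph
#' remains). Uses the current RNG state.
#'
#' @param sgs a `subgraph_set`.
#' @param ag masking probability in `[0, 1]`.
#' @return a `subgraph_set` of size |S| or |S| - 1.
#' @export
mask_subgraph <- function(sgs, ag) {
  stopifnot(ag >= 0, ag <= 1)
  if (ag == 0) return(sgs)
  r <- stats::runif(1) < ag
  if (!r) return(sgs)
  l <- length(sgs$graphs)
  if (l < 2L) {
    warning("mask_subgraph: only one sub-graph, skipping drop")
    return(sgs)
  }
  drop <- sample.int(l, 1L)
  keep <- setdiff(seq_len(l), drop)
  structure(list(graphs = sgs$graphs[keep], names = sgs$names[keep],
                 K = sgs$K[keep]),
            class = "subgraph_set")
}

#' Build the corrupted sub-graph set for one training epoch
#'
#' Pipeline: [mask_features()] on the HG, rebuild the sub-graphs on the
#' corrupted HG (with K values fixed from the clean graph), then
#' [mask_subgraph()] and [mask_edges()] on the survivors. Randomness comes
#' from a dedicated stream derived from `cfg$seed` and `epoch`, so two runs
#' with the same configuration produce identical sequences. The ablation
#' modes enable exactly one level ("f"/"e"/"g") or none ("none", in which case
#' the clean set is returned unchanged).
#'
#' @param hg the clean `drug_hg`.
#' @param sgs_clean the clean `subgraph_set` built from `hg`.
#' @param cfg an [aug_config()].
#' @param epoch epoch index (drives the random stream).
#' @return a corrupted `subgraph_set`.
#' @export
build_augmented_set <- function(hg, sgs_clean, cfg, epoch = 1L) {
  stopifnot(inherits(cfg, "aug_config"))
  if (cfg$mode == "none") return(sgs_clean)
  do_f <- cfg$mode %in% c("full", "f")
  do_e <- cfg$mode %in% c("full", "e")
  do_g <- cfg$mode %in% c("full", "g")
  with_seed(derive_seed(cfg$seed, epoch), {
    sgs <- if (do_f && cfg$af > 0) {
      hg2 <- mask_features(hg, cfg$af)
      build_subgraphs(hg2, specs = sgs_clean$names, K_overrides = sgs_clean$K)
    } else {
      sgs_clean
    }
    if (do_g) sgs <- mask_subgraph(sgs, cfg$ag)
    if (do_e) sgs <- mask_edges(sgs, cfg$ae)
    sgs
  })
}
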